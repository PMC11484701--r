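# Denoiser architectures: DnCNN-style residual CNN and U-Net-style
# encoder-decoder, both without normalization layers.

#' Denoiser architecture configuration
#'
#' @param family `"dncnn"` (stacked 3x3 convolutions + ReLU with a global
#'   residual connection) or `"unet"` (contracting/expanding path with skip
#'   connections). Neither uses normalization layers.
#' @param depth Number of convolution layers for `"dncnn"` (>= 3).
#' @param width Feature channels (`"dncnn"`) or base channels at the finest
#'   level (`"unet"`, doubled per level).
#' @param in_channels Input channels: the noisy target plus any guidance
#'   channels.
#' @param levels Resolution levels for `"unet"` (input sides must be
#'   divisible by `2^(levels - 1)`).
#' @param residual If `TRUE` the network predicts the noise, which is
#'   subtracted from the target channel (DnCNN convention; with small final
#'   weights the untrained model starts near the identity).
#' @return Object of class `denoiser_config`.
#' @export
denoiser_config <- function(family = c("dncnn", "unet"), depth = 17L,
                            width = 64L, in_channels = 2L, levels = 4L,
                            residual = TRUE) {
  family <- match.arg(family)
  if (family == "dncnn" && depth < 3) stop("dncnn depth must be >= 3")
  if (family == "unet" && levels < 2) stop("unet needs at least 2 levels")
  if (in_channels < 1) stop("in_channels must be >= 1")
  if (width < 1) stop("width must be >= 1")
  structure(list(family = family, depth = as.integer(depth),
                 width = as.integer(width),
                 in_channels = as.integer(in_channels),
                 levels = as.integer(levels), out_channels = 1L,
                 residual = isTRUE(residual)),
            class = "denoiser_config")
}

#' Build an (untrained) denoiser network
#'
#' Initialises the convolution weights (He initialisation; the final layer
#' is scaled down so a residual model starts near the identity map).
#'
#' @param config A [denoiser_config()].
#' @param seed Integer seed for the weight initialisation.
#' @return Object of class `denoiser_net` with elements `config`, `params`
#'   and `seed`.
#' @export
build_denoiser <- function(config = denoiser_config(), seed = 1L) {
  stopifnot(inherits(config, "denoiser_config"))
  set.seed(seed)
  params <- if (config$family == "dncnn")
    dncnn_init(config$depth, config$width, config$in_channels)
  else
    unet_init(config$levels, config$width, config$in_channels)
  structure(list(config = config, params = params, seed = as.integer(seed)),
            class = "denoiser_net")
}

#' Number of trainable parameters
#'
#' @param denoiser A `denoiser_net` or fitted `dwi_denoiser`.
#' @return Integer count of trainable scalars (weights and biases).
#' @export
count_parameters <- function(denoiser) {
  if (inherits(denoiser, "dwi_denoiser")) denoiser <- denoiser$net
  length(flatten_params(denoiser$params))
}

#' Apply a denoiser network to one sample
#'
#' @param net A `denoiser_net`.
#' @param target Noisy target image (matrix), fed as channel 1.
#' @param guidance Optional guidance image(s): matrix or list of matrices,
#'   concatenated as further channels. Channel count must match
#'   `net$config$in_channels`.
#' @return Denoised image (matrix, same shape as `target`).
#' @export
apply_denoiser <- function(net, target, guidance = NULL) {
  stopifnot(inherits(net, "denoiser_net"))
  H <- nrow(target); W <- ncol(target)
  if (is.matrix(guidance)) guidance <- list(guidance)
  X <- cbind(c(target),
             if (length(guidance))
               do.call(cbind, lapply(guidance, c)))
  if (ncol(X) != net$config$in_channels)
    stop("sample has ", ncol(X), " channels but the network expects ",
         net$config$in_channels)
  check_unet_size(net$config, H, W)
  matrix(net_fwd(net, X, H, W, 1L)$out, H, W)
}

check_unet_size <- function(config, H, W) {
  if (config$family != "unet") return(invisible())
  f <- 2^(config$levels - 1L)
  if (H %% f != 0 || W %% f != 0)
    stop("unet with ", config$levels, " levels needs image sides divisible by ",
         f, "; got ", H, "x", W)
}

# Plain function-of-an-image view of a network (guidance held fixed), for
# use with sure_loss() / mc_divergence().
#' Wrap a network as a plain image-to-image function
#'
#' Returns `function(y)` that denoises the matrix `y` with `net`, holding
#' the optional guidance channels fixed — the form expected by
#' [sure_loss()] and [mc_divergence()].
#'
#' @inheritParams apply_denoiser
#' @return A function mapping a matrix to a matrix.
#' @export
as_denoiser_function <- function(net, guidance = NULL) {
  force(net); force(guidance)
  function(y) apply_denoiser(net, y, guidance)
}

#' @export
print.denoiser_net <- function(x, ...) {
  cfg <- x$config
  cat("Denoiser network (", cfg$family, ")\n", sep = "")
  if (cfg$family == "dncnn")
    cat("  depth:", cfg$depth, " width:", cfg$width, "\n")
  else
    cat("  levels:", cfg$levels, " base width:", cfg$width, "\n")
  cat("  input channels:", cfg$in_channels,
      " residual:", cfg$residual, "\n")
  cat("  trainable parameters:", count_parameters(x), "\n")
  invisible(x)
}

#' Save / load a denoiser checkpoint
#'
#' Checkpoints are JSON files carrying the architecture configuration, the
#' flattened weights and the initialisation seed.
#'
#' @param net A `denoiser_net`.
#' @param path File path.
#' @return `load_denoiser` returns a `denoiser_net`.
#' @export
save_denoiser <- function(net, path) {
  stopifnot(inherits(net, "denoiser_net"))
  obj <- list(config = unclass(net$config), seed = net$seed,
              flat = flatten_params(net$params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_denoiser
#' @export
load_denoiser <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(denoiser_config, obj$config[c("family", "depth", "width",
                                               "in_channels", "levels",
                                               "residual")])
  net <- build_denoiser(cfg, seed = obj$seed)
  net$params <- unflatten_params(as.numeric(obj$flat), net$params)
  net
}
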