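# Training strategies: SURE (self-supervised, noise-map driven),
# Noise2Noise (split repetitions into input/reference halves) and Half2Full
# (half-average input, full-average reference), plus inference.

#' Training control parameters
#'
#' @param learning_rate Adam learning rate (paper-scale default `5e-5`;
#'   small desk-scale runs converge faster with larger rates).
#' @param batch_size Minibatch size.
#' @param max_epochs Upper bound on training epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param val_fraction Fraction of samples held out for validation.
#' @param repetition_fraction Fraction of target-b repetitions averaged into
#'   each training input (the noise map is rescaled for the actual count
#'   used).
#' @param guidance Use the matched-direction low-b image as an extra input
#'   channel?
#' @param normalize Divide each sample and its noise map by a per-sample
#'   robust scale (99th percentile of the guidance channel, or of the
#'   target when no guidance is used)? Joint scaling of image and sigma
#'   preserves the meaning of the SURE loss.
#' @param patch Optional patch side (pixels). Samples are tiled into
#'   non-overlapping `patch x patch` crops for training (the usual DnCNN
#'   regime: more, smaller optimisation steps for the same data). `NULL`
#'   trains on full images. Inference always runs on full images.
#' @param seed Integer seed governing initialisation, data shuffling and
#'   probe draws.
#' @param verbose Print per-epoch losses?
#' @return Object of class `train_control`.
#' @export
train_control <- function(learning_rate = 5e-5, batch_size = 64L,
                          max_epochs = 100L, patience = 10L,
                          val_fraction = 0.2, repetition_fraction = 1,
                          guidance = TRUE, normalize = TRUE, patch = NULL,
                          seed = 1L, verbose = FALSE) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (!(repetition_fraction > 0 && repetition_fraction <= 1))
    stop("repetition_fraction must be in (0, 1]")
  if (!is.null(patch) && patch < 8) stop("patch must be >= 8 pixels")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction,
                 repetition_fraction = repetition_fraction,
                 guidance = isTRUE(guidance), normalize = isTRUE(normalize),
                 patch = if (!is.null(patch)) as.integer(patch),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_control")
}

as_prep_list <- function(preps) {
  if (inherits(preps, "dwi_prep")) preps <- list(preps)
  if (!length(preps) || !all(vapply(preps, inherits, logical(1), "dwi_prep")))
    stop("preps must be a dwi_prep object or a list of them")
  preps
}

target_b_index <- function(prep) which.max(prep$b_values)
guidance_b_index <- function(prep) which.min(prep$b_values)

#' Build SURE training samples from preprocessed data
#'
#' One sample per (slice, direction): the target is the averaged
#' phase-corrected high-b image (from `ceiling(fraction * N)` repetitions),
#' the guidance channel is the matched-direction low-b average, and the
#' noise map is the blurred per-repetition noise std scaled by
#' `1/sqrt(n_used)`.
#'
#' @param preps A `dwi_prep` or list of them (slices).
#' @param repetition_fraction Fraction of target-b repetitions used.
#' @param guidance Include the matched-direction low-b guidance channel?
#' @return List of samples, each with `target`, `guidance` (or `NULL`),
#'   `sigma`, `slice`, `direction`.
#' @export
make_sure_dataset <- function(preps, repetition_fraction = 1,
                              guidance = TRUE) {
  preps <- as_prep_list(preps)
  samples <- list()
  for (s in seq_along(preps)) {
    prep <- preps[[s]]
    bt <- target_b_index(prep)
    bg <- guidance_b_index(prep)
    use_guid <- guidance && bg != bt
    for (d in seq_along(prep$directions)) {
      el <- prep$by_b[[bt]][[d]]
      if (is.null(el)) stop("missing direction ", prep$directions[d],
                            " at target b-value")
      n_used <- ceiling(repetition_fraction * el$n_reps)
      target <- average_repetitions(el$reps[, , seq_len(n_used), drop = FALSE])
      sigma <- el$sigma_rep / sqrt(n_used)
      guid <- NULL
      if (use_guid) {
        gel <- prep$by_b[[bg]][[d]]
        if (is.null(gel))
          stop("no matched guidance direction ", prep$directions[d],
               " at the low b-value")
        guid <- gel$avg
      }
      samples[[length(samples) + 1L]] <-
        list(target = target, guidance = guid, sigma = sigma,
             slice = s, direction = prep$directions[d], n_used = n_used)
    }
  }
  samples
}

# Noise2Noise / Half2Full samples. Repetitions are split by position parity
# (odd positions form the input half, even positions the reference half).
make_split_dataset <- function(preps, strategy, guidance = TRUE) {
  preps <- as_prep_list(preps)
  samples <- list()
  for (s in seq_along(preps)) {
    prep <- preps[[s]]
    bt <- target_b_index(prep)
    bg <- guidance_b_index(prep)
    use_guid <- guidance && bg != bt
    for (d in seq_along(prep$directions)) {
      el <- prep$by_b[[bt]][[d]]
      if (el$n_reps < 2)
        stop("cannot split a single repetition into input and reference")
      in_idx <- seq(1L, el$n_reps, by = 2L)
      ref_idx <- if (strategy == "noise2noise") seq(2L, el$n_reps, by = 2L)
                 else seq_len(el$n_reps)
      target <- average_repetitions(el$reps[, , in_idx, drop = FALSE])
      ref <- average_repetitions(el$reps[, , ref_idx, drop = FALSE])
      guid <- if (use_guid) prep$by_b[[bg]][[d]]$avg else NULL
      samples[[length(samples) + 1L]] <-
        list(target = target, reference = ref, guidance = guid,
             sigma = el$sigma_rep / sqrt(length(in_idx)),
             slice = s, direction = prep$directions[d],
             n_used = length(in_idx))
    }
  }
  samples
}

sample_scale <- function(sm) {
  base <- if (!is.null(sm$guidance)) sm$guidance else sm$target
  s <- as.numeric(stats::quantile(base, 0.99))
  if (!is.finite(s) || s <= 0) s <- max(abs(base), 1)
  s
}

normalize_sample <- function(sm, scale) {
  sm$target <- sm$target / scale
  if (!is.null(sm$guidance)) sm$guidance <- sm$guidance / scale
  if (!is.null(sm$sigma)) sm$sigma <- sm$sigma / scale
  if (!is.null(sm$reference)) sm$reference <- sm$reference / scale
  sm$scale <- scale
  sm
}

stack_channels <- function(samples) {
  do.call(rbind, lapply(samples, function(sm)
    cbind(c(sm$target),
          if (!is.null(sm$guidance)) c(sm$guidance))))
}

# One SURE loss + gradient evaluation on a batch; probe optionally fixed.
sure_batch <- function(net, samples, H, W, probe = NULL, want_grad = TRUE) {
  B <- length(samples)
  D <- H * W
  X1 <- stack_channels(samples)
  y <- X1[, 1L]
  sig2 <- unlist(lapply(samples, function(sm) c(sm$sigma)))^2
  eps <- max(y) * 1e-3
  if (eps <= 0) eps <- 1e-6
  if (is.null(probe)) probe <- sample(c(-1, 1), B * D, replace = TRUE)
  X2 <- X1
  X2[, 1L] <- X2[, 1L] + eps * probe
  s1 <- net_fwd(net, X1, H, W, B)
  s2 <- net_fwd(net, X2, H, W, B)
  f1 <- s1$out[, 1L]; f2 <- s2$out[, 1L]
  if (any(!is.finite(f1)) || any(!is.finite(f2)))
    stop("non-finite network output during SURE training (eps = ",
         signif(eps, 3), ", sigma range = [",
         signif(sqrt(min(sig2)), 3), ", ", signif(sqrt(max(sig2)), 3), "])")
  loss <- (sum((f1 - y)^2) + 2 * sum(probe * sig2 * (f2 - f1)) / eps) / (B * D)
  if (!want_grad) return(list(loss = loss))
  w <- 2 * sig2 * probe / (B * D * eps)
  d1 <- matrix(2 * (f1 - y) / (B * D) - w, ncol = 1L)
  d2 <- matrix(w, ncol = 1L)
  g1 <- net_bwd(net, s1, d1)
  g2 <- net_bwd(net, s2, d2)
  list(loss = loss,
       grad = flatten_params(g1) + flatten_params(g2))
}

mse_batch <- function(net, samples, H, W, want_grad = TRUE) {
  B <- length(samples)
  D <- H * W
  X <- stack_channels(samples)
  ref <- unlist(lapply(samples, function(sm) c(sm$reference)))
  s1 <- net_fwd(net, X, H, W, B)
  out <- s1$out[, 1L]
  if (any(!is.finite(out))) stop("non-finite network output during training")
  loss <- sum((out - ref)^2) / (B * D)
  if (!want_grad) return(list(loss = loss))
  dOut <- matrix(2 * (out - ref) / (B * D), ncol = 1L)
  list(loss = loss, grad = flatten_params(net_bwd(net, s1, dOut)))
}

#' Fit a self-supervised DWI denoiser
#'
#' The central fitting function. Builds training samples from preprocessed
#' repetition data, then trains a convolutional denoiser with one of three
#' self-supervised strategies:
#' \describe{
#'   \item{`"sure"`}{minimises the spatially variant SURE loss (constant
#'     term omitted), using the repetition-derived noise maps and a fresh
#'     Rademacher probe per step;}
#'   \item{`"noise2noise"`}{MSE between the output for the input-half
#'     average and the reference-half average;}
#'   \item{`"half2full"`}{MSE between the output for a 50%-repetition
#'     average and the full-repetition average.}
#' }
#' Validation loss is tracked on a held-out sample fraction and training
#' stops once it has not improved for `control$patience` epochs; the
#' best-validation weights are kept. The run is reproducible given
#' `control$seed`.
#'
#' @param preps A `dwi_prep` or list of them (one per slice), from
#'   [preprocess_stack()].
#' @param strategy Training strategy (see above).
#' @param model A [denoiser_config()] or a pre-built `denoiser_net`.
#' @param control A [train_control()].
#' @return Object of class `dwi_denoiser` with the trained network, the
#'   per-epoch loss history and the training configuration. Supports
#'   `print`, `summary`, `coef`, `predict`, `plot` and `residuals`.
#' @seealso [denoise()], [residual_report()]
#' @export
fit_denoiser <- function(preps, strategy = c("sure", "noise2noise",
                                             "half2full"),
                         model = denoiser_config(family = "dncnn", depth = 6L,
                                                 width = 32L),
                         control = train_control()) {
  strategy <- match.arg(strategy)
  preps <- as_prep_list(preps)
  stopifnot(inherits(control, "train_control"))

  samples <- if (strategy == "sure")
    make_sure_dataset(preps, control$repetition_fraction, control$guidance)
  else
    make_split_dataset(preps, strategy, control$guidance)
  if (!length(samples)) stop("no training samples could be built")
  H <- nrow(samples[[1]]$target); W <- ncol(samples[[1]]$target)

  n_chan <- 1L + as.integer(!is.null(samples[[1]]$guidance))
  if (inherits(model, "denoiser_config")) {
    if (model$in_channels != n_chan) model$in_channels <- n_chan
    net <- build_denoiser(model, seed = control$seed)
  } else if (inherits(model, "denoiser_net")) {
    net <- model
    if (net$config$in_channels != n_chan)
      stop("network expects ", net$config$in_channels,
           " channels but the data provides ", n_chan)
  } else stop("model must be a denoiser_config or denoiser_net")
  check_unet_size(net$config, H, W)

  if (control$normalize)
    samples <- lapply(samples, function(sm)
      normalize_sample(sm, sample_scale(sm)))

  if (!is.null(control$patch) && control$patch < min(H, W)) {
    samples <- crop_patches(samples, control$patch)
    H <- W <- control$patch
  }

  set.seed(control$seed + 1L)
  n <- length(samples)
  n_val <- if (n >= 5) max(1L, round(control$val_fraction * n)) else 0L
  val_idx <- if (n_val > 0) sample(n, n_val) else integer(0)
  train_idx <- setdiff(seq_len(n), val_idx)
  val_probe <- if (n_val > 0)
    sample(c(-1, 1), n_val * H * W, replace = TRUE)

  theta <- flatten_params(net$params)
  st <- adam_init(length(theta))
  skel <- net$params
  bsz <- min(control$batch_size, length(train_idx))

  eval_loss <- function(idx, probe = NULL) {
    if (strategy == "sure")
      sure_batch(net, samples[idx], H, W, probe, want_grad = FALSE)$loss
    else
      mse_batch(net, samples[idx], H, W, want_grad = FALSE)$loss
  }

  history <- data.frame(epoch = integer(0), train = numeric(0),
                        val = numeric(0))
  best_val <- Inf; best_theta <- theta; best_epoch <- 0L; wait <- 0L
  for (epoch in seq_len(control$max_epochs)) {
    ord <- sample(train_idx)
    tr_loss <- 0; n_batches <- 0L
    for (start in seq(1L, length(ord), by = bsz)) {
      bidx <- ord[start:min(start + bsz - 1L, length(ord))]
      res <- if (strategy == "sure")
        sure_batch(net, samples[bidx], H, W)
      else
        mse_batch(net, samples[bidx], H, W)
      up <- adam_step(theta, res$grad, st, control$learning_rate)
      theta <- up$theta; st <- up$state
      net$params <- unflatten_params(theta, skel)
      tr_loss <- tr_loss + res$loss; n_batches <- n_batches + 1L
    }
    tr_loss <- tr_loss / n_batches
    vl <- if (n_val > 0) eval_loss(val_idx, val_probe) else tr_loss
    history <- rbind(history,
                     data.frame(epoch = epoch, train = tr_loss, val = vl))
    if (control$verbose)
      message(sprintf("epoch %3d  train %.6g  val %.6g", epoch, tr_loss, vl))
    if (vl < best_val - 1e-12) {
      best_val <- vl; best_theta <- theta; best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= control$patience) break
    }
  }
  net$params <- unflatten_params(best_theta, skel)

  structure(list(net = net, strategy = strategy, control = control,
                 history = history, best_epoch = best_epoch,
                 best_val = best_val, samples = samples,
                 H = H, W = W, n_channels = n_chan),
            class = "dwi_denoiser")
}

# Tile samples into non-overlapping square patches (leftover margins along
# the bottom/right edges are dropped).
crop_patches <- function(samples, patch) {
  out <- list()
  for (sm in samples) {
    H <- nrow(sm$target); W <- ncol(sm$target)
    for (i0 in seq(1L, H - patch + 1L, by = patch))
      for (j0 in seq(1L, W - patch + 1L, by = patch)) {
        ri <- i0:(i0 + patch - 1L); ci <- j0:(j0 + patch - 1L)
        p <- sm
        p$target <- sm$target[ri, ci]
        if (!is.null(sm$guidance)) p$guidance <- sm$guidance[ri, ci]
        if (!is.null(sm$sigma)) p$sigma <- sm$sigma[ri, ci]
        if (!is.null(sm$reference)) p$reference <- sm$reference[ri, ci]
        out[[length(out) + 1L]] <- p
      }
  }
  out
}

# Inference samples: full-repetition averages with matching noise maps.
infer_samples <- function(preps, guidance = TRUE) {
  preps <- as_prep_list(preps)
  samples <- list()
  for (s in seq_along(preps)) {
    prep <- preps[[s]]
    bt <- target_b_index(prep)
    bg <- guidance_b_index(prep)
    use_guid <- guidance && bg != bt
    for (d in seq_along(prep$directions)) {
      el <- prep$by_b[[bt]][[d]]
      samples[[length(samples) + 1L]] <-
        list(target = structure(el$avg, n_reps = NULL),
             guidance = if (use_guid) prep$by_b[[bg]][[d]]$avg else NULL,
             sigma = el$sigma_avg, slice = s,
             direction = prep$directions[d], n_used = el$n_reps)
    }
  }
  samples
}

denoise_samples <- function(object, samples) {
  lapply(samples, function(sm) {
    scale <- if (object$control$normalize) sample_scale(sm) else 1
    nsm <- normalize_sample(sm, scale)
    out <- apply_denoiser(object$net, nsm$target, nsm$guidance)
    sm$denoised <- out * scale
    sm
  })
}

#' Denoise preprocessed DWI data with a fitted model
#'
#' Applies a fitted denoiser to the full-repetition averaged direction
#' images of one or more slices and combines the per-direction outputs into
#' a trace image (geometric mean).
#'
#' @param object A fitted `dwi_denoiser`.
#' @param preps A `dwi_prep` or list of them.
#' @return A list per slice with `directions` (named list of denoised
#'   images), `noisy` (the inputs), `sigma` (noise maps of the averages)
#'   and `trace` (denoised trace image).
#' @export
denoise <- function(object, preps) {
  stopifnot(inherits(object, "dwi_denoiser"))
  preps <- as_prep_list(preps)
  samples <- denoise_samples(object,
                             infer_samples(preps, object$control$guidance))
  out <- list()
  for (s in seq_along(preps)) {
    sl <- Filter(function(sm) sm$slice == s, samples)
    dirs <- lapply(sl, `[[`, "denoised")
    names(dirs) <- vapply(sl, `[[`, character(1), "direction")
    noisy <- lapply(sl, `[[`, "target")
    names(noisy) <- names(dirs)
    sig <- lapply(sl, `[[`, "sigma")
    names(sig) <- names(dirs)
    out[[s]] <- list(directions = dirs, noisy = noisy, sigma = sig,
                     trace = trace_image(dirs))
  }
  out
}
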