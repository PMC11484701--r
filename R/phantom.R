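# Synthetic DWI phantom with known ground truth.
#
# Each repetition of one (b-value, direction) is
#   clean * exp(i * (phase_bg + phase_rep)) + complex Gaussian noise,
# where clean = S0 * exp(-b * ADC_dir), phase_bg is a smooth polynomial
# background phase shared by all repetitions, phase_rep is a low-order
# per-repetition phase instability, and the noise has per-pixel standard
# deviation sigma_map in both the real and imaginary channels.

#' Configuration of the synthetic DWI phantom
#'
#' Describes a piecewise-smooth prostate-like slice built from nested
#' ellipses with distinct baseline signal (`s0`) and apparent diffusion
#' coefficient (`adc`), imaged at several b-values with repeated
#' acquisitions per diffusion direction.
#'
#' @param grid_size Image size in pixels, `c(H, W)` (a single number is
#'   recycled to a square grid).
#' @param b_values Diffusion weightings in s/mm^2.
#' @param n_directions Number of diffusion-encoding directions.
#' @param n_repetitions Repetitions acquired per b-value (recycled to
#'   `length(b_values)`); at least 2 each so noise maps can be estimated.
#' @param adc_range Admissible ADC interval in mm^2/s; per-ellipse ADCs and
#'   their per-direction anisotropic variants are clipped to it.
#' @param s0_profile List of ellipses, each
#'   `list(cx, cy, rx, ry, s0, adc)` in normalised `[-1, 1]` coordinates;
#'   later ellipses overwrite earlier ones. The default nests a body, a
#'   central zone and a small focal lesion with restricted diffusion.
#' @param phase_order Polynomial order of the smooth background phase.
#' @param rep_phase_scale Magnitude (radians) of the random per-repetition
#'   phase instability; 0 disables it.
#' @param sigma_profile Smooth noise std map descriptor:
#'   `list(type = "radial", min, max)` gives a radial ramp from `min` at
#'   the image centre to `max` at the farthest corner (a surrogate for
#'   parallel-imaging g-factor amplification); `min == max` gives a
#'   constant map.
#' @param seed Integer seed; the phantom is reproducible given the seed.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_size = c(64L, 64L),
                           b_values = c(50, 1000),
                           n_directions = 3L,
                           n_repetitions = c(4L, 12L),
                           adc_range = c(5e-4, 2.5e-3),
                           s0_profile = default_s0_profile(),
                           phase_order = 2L,
                           rep_phase_scale = 0.3,
                           sigma_profile = list(type = "radial",
                                                min = 0.02, max = 0.08),
                           seed = 1L) {
  if (length(grid_size) == 1L) grid_size <- rep(grid_size, 2L)
  n_repetitions <- rep_len(as.integer(n_repetitions), length(b_values))
  stopifnot(all(grid_size >= 8), n_directions >= 1,
            length(b_values) >= 1, all(b_values >= 0))
  if (any(n_repetitions < 2))
    stop("n_repetitions must be >= 2 for every b-value")
  if (!(adc_range[1] > 0 && adc_range[2] >= adc_range[1]))
    stop("adc_range must be a positive interval")
  if (is.null(sigma_profile$min) || is.null(sigma_profile$max) ||
      sigma_profile$min < 0 || sigma_profile$max < 0)
    stop("sigma_profile min/max must be non-negative")
  if (sigma_profile$min > sigma_profile$max)
    stop("sigma_profile min must not exceed max")
  structure(list(grid_size = as.integer(grid_size), b_values = b_values,
                 n_directions = as.integer(n_directions),
                 n_repetitions = n_repetitions, adc_range = adc_range,
                 s0_profile = s0_profile, phase_order = as.integer(phase_order),
                 rep_phase_scale = rep_phase_scale,
                 sigma_profile = sigma_profile, seed = as.integer(seed)),
            class = "phantom_config")
}

#' @rdname phantom_config
#' @export
default_s0_profile <- function() {
  list(list(cx = 0.00, cy = 0.00, rx = 0.78, ry = 0.62, s0 = 1.00, adc = 2.0e-3),
       list(cx = 0.00, cy = -0.08, rx = 0.42, ry = 0.30, s0 = 1.25, adc = 1.4e-3),
       list(cx = 0.30, cy = 0.18, rx = 0.13, ry = 0.10, s0 = 1.10, adc = 0.7e-3))
}

# Normalised coordinate grids in [-1, 1].
norm_coords <- function(H, W) {
  x <- if (W > 1) seq(-1, 1, length.out = W) else 0
  y <- if (H > 1) seq(-1, 1, length.out = H) else 0
  list(X = matrix(x, H, W, byrow = TRUE), Y = matrix(y, H, W))
}

# 2-D polynomial field sum coef_k * X^a * Y^b over a + b <= order.
poly2d <- function(H, W, coefs, order) {
  g <- norm_coords(H, W)
  out <- matrix(0, H, W)
  k <- 0L
  for (a in 0:order) for (b in 0:(order - a)) {
    k <- k + 1L
    out <- out + coefs[k] * g$X^a * g$Y^b
  }
  out
}

n_poly_terms <- function(order) (order + 1L) * (order + 2L) / 2L

#' Smooth per-pixel noise standard-deviation map
#'
#' Builds the strictly positive sigma-map prescribed by the phantom
#' configuration (radial ramp or constant). Deterministic: no random draws
#' are involved.
#'
#' @param config A [phantom_config()].
#' @return `H x W` matrix of per-pixel noise standard deviations.
#' @export
generate_sigma_map <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  H <- config$grid_size[1]; W <- config$grid_size[2]
  p <- config$sigma_profile
  if (identical(p$min, p$max)) return(matrix(p$min, H, W))
  g <- norm_coords(H, W)
  r <- sqrt(g$X^2 + g$Y^2)
  r <- (r - min(r)) / (max(r) - min(r))  # hit min/max exactly on the grid
  p$min + (p$max - p$min) * r
}

# Rasterise the ellipse profile into S0 and base ADC maps.
rasterise_profile <- function(config) {
  H <- config$grid_size[1]; W <- config$grid_size[2]
  g <- norm_coords(H, W)
  s0 <- matrix(0, H, W); adc <- matrix(config$adc_range[1], H, W)
  for (e in config$s0_profile) {
    inside <- ((g$X - e$cx) / e$rx)^2 + ((g$Y - e$cy) / e$ry)^2 <= 1
    s0[inside] <- e$s0
    adc[inside] <- min(max(e$adc, config$adc_range[1]), config$adc_range[2])
  }
  list(s0 = s0, adc = adc)
}

#' Generate a synthetic DWI repetition stack with ground truth
#'
#' Draws the complete phantom: clean per-direction signal decay
#' `S0 * exp(-b * ADC)`, a smooth polynomial background phase, independent
#' per-repetition phase instabilities, and zero-mean complex Gaussian noise
#' with spatially varying standard deviation in both channels. All
#' randomness is driven by `config$seed`, so identical configurations give
#' bit-identical stacks.
#'
#' @param config A [phantom_config()].
#' @return A list with components `truth` (class `phantom_truth`: `s0`,
#'   `adc` per direction, `phase_bg`, `phase_rep`, `sigma_map`, and `clean`
#'   images per b-value and direction) and `stack` (class `rep_stack`:
#'   complex `H x W x N` arrays indexed by b-value and direction).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  H <- config$grid_size[1]; W <- config$grid_size[2]
  nb <- length(config$b_values); nd <- config$n_directions
  set.seed(config$seed)

  sigma_map <- generate_sigma_map(config)
  prof <- rasterise_profile(config)

  # mild per-direction anisotropy of the ADC
  dir_factor <- stats::runif(nd, 0.9, 1.1)
  adc <- array(0, c(H, W, nd))
  for (d in seq_len(nd))
    adc[, , d] <- pmin(pmax(prof$adc * dir_factor[d], config$adc_range[1]),
                       config$adc_range[2])

  nt <- n_poly_terms(config$phase_order)
  phase_bg <- poly2d(H, W, stats::runif(nt, -0.5, 0.5) * pi, config$phase_order)

  clean <- vector("list", nb)
  data <- vector("list", nb)
  phase_rep <- vector("list", nb)
  for (bi in seq_len(nb)) {
    b <- config$b_values[bi]; N <- config$n_repetitions[bi]
    clean[[bi]] <- array(0, c(H, W, nd))
    data[[bi]] <- vector("list", nd)
    phase_rep[[bi]] <- vector("list", nd)
    for (d in seq_len(nd)) {
      cl <- prof$s0 * exp(-b * adc[, , d])
      clean[[bi]][, , d] <- cl
      reps <- array(0i, c(H, W, N))
      preps <- array(0, c(H, W, N))
      for (j in seq_len(N)) {
        pr <- if (config$rep_phase_scale > 0)
          poly2d(H, W, stats::runif(3, -1, 1) * config$rep_phase_scale, 1L)
        else matrix(0, H, W)
        preps[, , j] <- pr
        noise <- (stats::rnorm(H * W) + 1i * stats::rnorm(H * W)) * c(sigma_map)
        reps[, , j] <- cl * exp(1i * (phase_bg + pr)) + noise
      }
      data[[bi]][[d]] <- reps
      phase_rep[[bi]][[d]] <- preps
    }
  }

  dir_labels <- paste0("dir", seq_len(nd))
  truth <- structure(list(s0 = prof$s0, adc = adc, phase_bg = phase_bg,
                          phase_rep = phase_rep, sigma_map = sigma_map,
                          clean = clean, b_values = config$b_values,
                          directions = dir_labels),
                     class = "phantom_truth")
  stack <- structure(list(data = data, b_values = config$b_values,
                          directions = dir_labels, H = H, W = W,
                          n_repetitions = config$n_repetitions,
                          seed = config$seed),
                     class = "rep_stack")
  list(truth = truth, stack = stack)
}

#' @export
print.rep_stack <- function(x, ...) {
  cat("DWI repetition stack:", x$H, "x", x$W, "pixels\n")
  for (bi in seq_along(x$b_values))
    cat(sprintf("  b=%g s/mm^2: %d directions x %d repetitions\n",
                x$b_values[bi], length(x$directions), x$n_repetitions[bi]))
  invisible(x)
}
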