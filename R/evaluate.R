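# Self-supervised evaluation: statistics of the noise-map-corrected
# residual, plus oracle metrics available only when ground truth exists.
#
# If a denoiser removes exactly the injected noise, the residual
# (noisy - denoised) divided by the noise map is standard normal: variance
# 1 and maximal Gaussian log-likelihood. Under-denoising gives variance
# below 1; removing image content makes the residual non-Gaussian.

#' Noise-map-corrected residual
#'
#' Computes `r = (noisy - denoised) / sigma` on pixels where the noise map
#' exceeds `mask_threshold * max(sigma)`; low-noise pixels are excluded to
#' avoid division blow-up.
#'
#' @param noisy Noisy input image (matrix).
#' @param denoised Denoised output (matrix, same shape).
#' @param noise_map Per-pixel noise standard deviation (matrix, same shape).
#' @param mask_threshold Fraction of `max(noise_map)` below which pixels
#'   are masked out (`0 <= mask_threshold < 1`).
#' @return List with `residual` (matrix; `NA` outside the mask) and `mask`
#'   (logical matrix).
#' @export
corrected_residual <- function(noisy, denoised, noise_map,
                               mask_threshold = 0.05) {
  if (!identical(dim(noisy), dim(denoised)) ||
      !identical(dim(noisy), dim(noise_map)))
    stop("noisy, denoised and noise_map must share one shape")
  if (!(mask_threshold >= 0 && mask_threshold < 1))
    stop("mask_threshold must be in [0, 1)")
  mask <- noise_map > mask_threshold * max(noise_map)
  if (!any(mask))
    stop("the noise-level mask excludes every pixel; lower mask_threshold")
  r <- matrix(NA_real_, nrow(noisy), ncol(noisy))
  r[mask] <- (noisy[mask] - denoised[mask]) / noise_map[mask]
  list(residual = r, mask = mask)
}

#' Variance of the corrected residual
#'
#' Sample variance over masked pixels; close to 1 for ideal denoising,
#' below 1 when noise is left in the image.
#'
#' @param residual Residual matrix (or vector).
#' @param mask Optional logical mask selecting the evaluated pixels.
#' @return Scalar variance.
#' @export
residual_variance <- function(residual, mask = NULL) {
  v <- if (is.null(mask)) residual[!is.na(residual)] else residual[mask]
  if (length(v) < 2) stop("need at least 2 masked pixels")
  stats::var(v)
}

#' Mean Gaussian log-likelihood of the corrected residual
#'
#' Mean over masked pixels of `log phi(r) = -r^2/2 - log(2*pi)/2` with
#' `phi` the standard normal density. Reported per pixel so values are
#' comparable across image sizes; a standard normal residual scores about
#' `-(1 + log(2*pi))/2 = -1.4189`, and the score is maximal (`-0.9189`)
#' only for an exactly zero residual.
#'
#' @inheritParams residual_variance
#' @return Scalar mean log-likelihood.
#' @export
residual_gaussian_loglik <- function(residual, mask = NULL) {
  v <- if (is.null(mask)) residual[!is.na(residual)] else residual[mask]
  if (length(v) < 1) stop("degenerate mask: no pixels to evaluate")
  mean(-0.5 * v^2 - 0.5 * log(2 * pi))
}

#' Oracle mean squared error against known ground truth
#'
#' Only meaningful for synthetic data where the clean image is known.
#'
#' @param denoised Denoised image (matrix).
#' @param clean Ground-truth clean image (matrix, same shape), or a
#'   `phantom_truth` together with `b_index`/`dir_index`.
#' @param b_index,dir_index Indices selecting the clean image when `clean`
#'   is a `phantom_truth`.
#' @return Scalar `(1/D) * ||denoised - clean||^2`.
#' @export
oracle_mse <- function(denoised, clean, b_index = NULL, dir_index = NULL) {
  if (inherits(clean, "phantom_truth"))
    clean <- clean$clean[[b_index]][, , dir_index]
  if (!identical(dim(denoised), dim(clean)))
    stop("denoised and clean must share one shape")
  mean((denoised - clean)^2)
}

#' Residual evaluation report
#'
#' Bundles the self-supervised residual statistics of a denoising result.
#'
#' @inheritParams corrected_residual
#' @return Object of class `residual_report` with `variance`,
#'   `gaussian_loglik`, `n_pixels` and `mask_fraction`.
#' @export
residual_report <- function(noisy, denoised, noise_map,
                            mask_threshold = 0.05) {
  cr <- corrected_residual(noisy, denoised, noise_map, mask_threshold)
  structure(list(variance = residual_variance(cr$residual, cr$mask),
                 gaussian_loglik = residual_gaussian_loglik(cr$residual,
                                                            cr$mask),
                 n_pixels = sum(cr$mask),
                 mask_fraction = mean(cr$mask)),
            class = "residual_report")
}

#' @export
print.residual_report <- function(x, ...) {
  cat("Corrected-residual evaluation\n")
  cat(sprintf("  variance:        %.4f (ideal: 1.0)\n", x$variance))
  cat(sprintf("  log-likelihood:  %.4f per pixel\n", x$gaussian_loglik))
  cat(sprintf("  pixels:          %d (%.1f%% of image)\n",
              x$n_pixels, 100 * x$mask_fraction))
  invisible(x)
}
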