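# Preprocessing chain: phase correction, complex averaging, repetition-derived
# noise maps, and the geometric-mean trace image.

#' Low-frequency phase of a complex image
#'
#' Boxcar-filters the real and imaginary channels separately (mirror
#' boundary) and returns the argument of the filtered complex image. With
#' `kernel = 1` this is the pixelwise phase of the input.
#'
#' @param image Complex matrix.
#' @param kernel Odd boxcar window size in pixels.
#' @return Matrix of phases in radians.
#' @export
lowfreq_phase <- function(image, kernel = 15L) {
  if (kernel < 1 || kernel %% 2 == 0)
    stop("kernel must be an odd positive integer, got ", kernel)
  if (kernel == 1L) return(Arg(image))
  Arg(boxcar_filter(Re(image), kernel) + 1i * boxcar_filter(Im(image), kernel))
}

#' Phase correction by complex rotation
#'
#' Rotates a complex image by its estimated low-frequency phase so that the
#' signal of interest lies in the real channel. The rotation is unitary, so
#' zero-mean complex Gaussian noise keeps its distribution; the corrected
#' imaginary channel then contains noise only and can be discarded.
#'
#' @inheritParams lowfreq_phase
#' @return List with `real` (signal + Gaussian noise), `imag` (discarded
#'   noise-only channel) and `phase` (the estimate that was removed).
#' @export
phase_correct <- function(image, kernel = 15L) {
  ph <- lowfreq_phase(image, kernel)
  rot <- image * exp(-1i * ph)
  list(real = Re(rot), imag = Im(rot), phase = ph)
}

#' Arithmetic mean across repetitions
#'
#' @param reps Real `H x W x N` array of phase-corrected repetitions (a
#'   single matrix is treated as `N = 1`).
#' @return Mean image with attribute `n_reps` recording the count used.
#' @export
average_repetitions <- function(reps) {
  if (is.matrix(reps)) reps <- array(reps, c(dim(reps), 1L))
  if (length(dim(reps)) != 3L || dim(reps)[3] < 1L)
    stop("reps must be a non-empty H x W x N array")
  out <- rowMeans(reps, dims = 2L)
  attr(out, "n_reps") <- dim(reps)[3]
  out
}

#' Mean of magnitude images across repetitions
#'
#' Magnitude averaging of complex repetitions. In zero-signal regions the
#' per-repetition magnitude is Rayleigh distributed, so the average has a
#' raised noise floor of about `1.2533 * sigma` instead of zero — the
#' Rician bias that complex averaging avoids.
#'
#' @param reps Complex `H x W x N` array.
#' @return Real mean-magnitude image.
#' @export
magnitude_average <- function(reps) {
  if (is.matrix(reps)) reps <- array(reps, c(dim(reps), 1L))
  if (length(dim(reps)) != 3L || dim(reps)[3] < 1L)
    stop("reps must be a non-empty H x W x N array")
  rowMeans(Mod(reps), dims = 2L)
}

#' Noise map from repeated acquisitions
#'
#' Per-pixel sample standard deviation across phase-corrected repetitions
#' (denominator `N - 1`), scaled by `1/sqrt(N)` so that it describes the
#' noise level of the N-repetition average, then Gaussian-blurred
#' (`blur_sigma`, default 10 pixels) to keep the overall spatial noise
#' distribution rather than local high-frequency fluctuations of the
#' estimate. `blur_sigma = 0` disables the blur.
#'
#' @param reps Real `H x W x N` array, `N >= 2`.
#' @param blur_sigma Gaussian blur std in pixels.
#' @return Non-negative matrix with attribute `provenance = "from_repetitions"`.
#' @export
noise_map_from_repetitions <- function(reps, blur_sigma = 10) {
  if (is.matrix(reps) || dim(reps)[3] < 2L)
    stop("at least 2 repetitions are required to estimate a noise map; ",
         "supply an external noise map instead (see accept_external_noise_map)")
  N <- dim(reps)[3]
  m <- rowMeans(reps, dims = 2L)
  s2 <- (rowSums(reps^2, dims = 2L) - N * m^2) / (N - 1)
  map <- sqrt(pmax(s2, 0)) / sqrt(N)
  if (blur_sigma > 0) map <- pmax(gaussian_blur(map, blur_sigma), 0)
  attr(map, "provenance") <- "from_repetitions"
  map
}

#' Use an externally supplied noise map
#'
#' Accepts a ready-made per-pixel noise standard-deviation map (e.g. one
#' propagated from a scanner noise adjustment scan) for the averaged,
#' phase-corrected image. `scale` absorbs any scaling needed to account for
#' phase correction and image averaging (such as `1/sqrt(N)`).
#'
#' @param map Matrix of noise standard deviations, or a path to a NIfTI
#'   file holding one.
#' @param scale Positive multiplicative factor.
#' @param shape Optional `c(H, W)` the map must match.
#' @return Matrix with attribute `provenance = "external"`.
#' @export
accept_external_noise_map <- function(map, scale = 1, shape = NULL) {
  if (is.character(map)) map <- read_map(map)
  if (!is.matrix(map)) stop("map must be a matrix or a NIfTI file path")
  if (scale <= 0) stop("scale must be positive")
  if (!is.null(shape) && !identical(dim(map), as.integer(shape)))
    stop("noise map shape ", paste(dim(map), collapse = "x"),
         " does not match image grid ", paste(shape, collapse = "x"))
  out <- map * scale
  if (any(out < 0))
    warning("external noise map contains negative values after scaling")
  attr(out, "provenance") <- "external"
  out
}

#' Trace image (geometric mean over directions)
#'
#' Pixelwise geometric mean of per-direction images. Negative pixels (which
#' can occur after phase correction) are clipped to zero before the product
#' so the root is defined; any zero direction gives a zero trace pixel.
#'
#' @param direction_images List of real matrices (or an `H x W x n` array),
#'   one per diffusion direction, on a common grid.
#' @return Real matrix.
#' @export
trace_image <- function(direction_images) {
  if (is.array(direction_images) && length(dim(direction_images)) == 3L)
    direction_images <- lapply(seq_len(dim(direction_images)[3]),
                               function(k) direction_images[, , k])
  if (!is.list(direction_images) || length(direction_images) == 0L)
    stop("direction_images must be a non-empty list of matrices")
  dims <- lapply(direction_images, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all direction images must share the same shape")
  n <- length(direction_images)
  acc <- matrix(0, nrow(direction_images[[1]]), ncol(direction_images[[1]]))
  for (img in direction_images) acc <- acc + log(pmax(img, 0))
  exp(acc / n)
}

#' Preprocess a repetition stack for training
#'
#' Runs the full preprocessing chain on every (b-value, direction) of a
#' repetition stack: phase correction of each repetition, complex
#' (arithmetic) averaging of the corrected real channels, and
#' repetition-derived noise maps.
#'
#' @param stack A `rep_stack` (see [generate_phantom()] or [read_stack()]).
#' @param kernel Boxcar window for the low-frequency phase estimate.
#' @param blur_sigma Gaussian blur std (pixels) for the noise maps.
#' @return Object of class `dwi_prep`: per b-value and direction the
#'   corrected repetitions (`reps`), their average (`avg`), the blurred
#'   per-repetition noise std (`sigma_rep`, unscaled) and the noise map of
#'   the average (`sigma_avg = sigma_rep / sqrt(N)`).
#' @export
preprocess_stack <- function(stack, kernel = 15L, blur_sigma = 10) {
  stopifnot(inherits(stack, "rep_stack"))
  out <- vector("list", length(stack$b_values))
  for (bi in seq_along(stack$b_values)) {
    out[[bi]] <- vector("list", length(stack$directions))
    for (d in seq_along(stack$directions)) {
      creps <- stack$data[[bi]][[d]]
      N <- dim(creps)[3]
      reps <- array(0, dim(creps))
      for (j in seq_len(N))
        reps[, , j] <- phase_correct(creps[, , j], kernel)$real
      avg <- average_repetitions(reps)
      sigma_avg <- noise_map_from_repetitions(reps, blur_sigma)
      list_el <- list(reps = reps, avg = avg, n_reps = N,
                      sigma_rep = sigma_avg * sqrt(N), sigma_avg = sigma_avg)
      out[[bi]][[d]] <- list_el
    }
  }
  structure(list(by_b = out, b_values = stack$b_values,
                 directions = stack$directions, H = stack$H, W = stack$W,
                 kernel = kernel, blur_sigma = blur_sigma),
            class = "dwi_prep")
}
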