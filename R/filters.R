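# Separable image filters with mirror (reflect) boundary handling.
# Mirror padding avoids the edge darkening that zero padding produces on
# small fields of view; kernels can be wider than the image (indices fold
# repeatedly).

#' @keywords internal
reflect_index <- function(n, i) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- (i - 1L) %% (2L * (n - 1L))
  ifelse(p < n, p + 1L, 2L * n - 1L - p)
}

# 2-D separable convolution of a real matrix with a symmetric 1-D kernel
# applied along rows then columns.
#' @keywords internal
sep_filter <- function(img, kern) {
  r <- (length(kern) - 1L) %/% 2L
  if (r == 0L) return(img * kern)
  H <- nrow(img); W <- ncol(img)
  pad <- img[reflect_index(H, (1L - r):(H + r)), , drop = FALSE]
  tmp <- matrix(0, H, W)
  for (t in seq_along(kern))
    tmp <- tmp + kern[t] * pad[(t - 1L) + seq_len(H), , drop = FALSE]
  pad <- tmp[, reflect_index(W, (1L - r):(W + r)), drop = FALSE]
  out <- matrix(0, H, W)
  for (t in seq_along(kern))
    out <- out + kern[t] * pad[, (t - 1L) + seq_len(W), drop = FALSE]
  out
}

#' Boxcar (uniform) filter of a real image
#'
#' Uniformly weighted moving average over a `size` x `size` window with
#' mirror boundary handling, as used to extract the low-frequency phase
#' before complex averaging.
#'
#' @param img Real matrix.
#' @param size Odd window size in pixels (`size = 1` returns the input).
#' @return Filtered matrix of the same shape.
#' @export
boxcar_filter <- function(img, size) {
  if (size < 1 || size %% 2 == 0)
    stop("boxcar size must be an odd positive integer, got ", size)
  sep_filter(img, rep(1 / size, size))
}

#' Gaussian blur of a real image
#'
#' Separable Gaussian filter with mirror boundary handling; the kernel is
#' truncated at three standard deviations. `sigma = 0` returns the input
#' unchanged.
#'
#' @param img Real matrix.
#' @param sigma Standard deviation of the Gaussian kernel, in pixels.
#' @return Filtered matrix of the same shape.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma < 0) stop("blur sigma must be >= 0")
  if (sigma == 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  sep_filter(img, k / sum(k))
}
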