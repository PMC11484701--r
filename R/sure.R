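# Stein's unbiased risk estimator (SURE) for spatially variant Gaussian
# noise, and its Monte-Carlo divergence estimator.
#
# For y ~ N(x, Sigma) with diagonal Sigma (Sigma_dd = sigma_d^2) and a
# denoiser f, the expected MSE against the unknown clean image x equals
#
#   E (1/D) ( ||f(y) - y||^2 - sum_d sigma_d^2
#             + 2 div_y( sigma^2 (*) f(y) ) ),
#
# where (*) is elementwise multiplication. The divergence is estimated by
# a finite-difference probe:
#
#   div_y( sigma^2 (*) f(y) ) ~ b^T ( sigma^2 (*) (f(y + eps b) - f(y)) / eps )
#
# with b a zero-mean, unit-variance i.i.d. random vector.

#' SURE loss configuration
#'
#' @param epsilon Either the string `"max_y_1e-3"` (probe step
#'   `eps = max(y) * 1e-3`, taken over the batch) or a fixed positive value.
#' @param probe Probe distribution for the Monte-Carlo divergence:
#'   `"rademacher"` (+/-1, exact for diagonal operators) or `"gaussian"`.
#' @param include_constant Include the `-sum(sigma^2)` constant? It does
#'   not affect gradients; include it when comparing SURE values to MSE,
#'   drop it in the training objective.
#' @param n_probes Number of probes averaged per evaluation (1 during
#'   stochastic training; more for low-variance validation estimates).
#' @param probe_seed Optional integer seed for the probe draws.
#' @return Object of class `sure_config`.
#' @export
sure_config <- function(epsilon = "max_y_1e-3",
                        probe = c("rademacher", "gaussian"),
                        include_constant = FALSE,
                        n_probes = 1L,
                        probe_seed = NULL) {
  probe <- match.arg(probe)
  if (is.numeric(epsilon) && epsilon <= 0) stop("fixed epsilon must be > 0")
  if (is.character(epsilon) && !identical(epsilon, "max_y_1e-3"))
    stop("epsilon must be \"max_y_1e-3\" or a positive number")
  structure(list(epsilon = epsilon, probe = probe,
                 include_constant = isTRUE(include_constant),
                 n_probes = as.integer(n_probes), probe_seed = probe_seed),
            class = "sure_config")
}

resolve_epsilon <- function(cfg, y) {
  if (is.numeric(cfg$epsilon)) return(cfg$epsilon)
  m <- if (is.list(y)) max(vapply(y, max, numeric(1))) else max(y)
  eps <- m * 1e-3
  if (eps <= 0) stop("epsilon rule max(y)*1e-3 gave a non-positive step; ",
                     "supply a fixed epsilon")
  eps
}

draw_probe <- function(n, probe) {
  if (probe == "rademacher") sample(c(-1, 1), n, replace = TRUE)
  else stats::rnorm(n)
}

#' Monte-Carlo estimate of the sigma^2-weighted divergence
#'
#' Estimates `div_y(sigma^2 (*) f(y))` by a randomized finite difference:
#' `b^T (sigma^2 (*) (f(y + eps b) - f(y)) / eps)`. A fresh probe is drawn
#' per call (and per list element when `y` is a batch).
#'
#' @param denoiser Function mapping a real matrix to a real matrix of the
#'   same shape.
#' @param y Real matrix, or a list of matrices (a batch).
#' @param sigma2 Matrix of per-pixel noise variances, same shape as `y`.
#' @param cfg A [sure_config()].
#' @param epsilon Optional fixed probe step overriding the config rule
#'   (used to share one per-batch step across images).
#' @return Scalar divergence estimate per image (vector for a batch).
#' @export
mc_divergence <- function(denoiser, y, sigma2, cfg = sure_config(),
                          epsilon = NULL) {
  if (!is.null(cfg$probe_seed)) set.seed(cfg$probe_seed)
  if (is.list(y))
    return(vapply(y, function(yi)
      mc_divergence_one(denoiser, yi, sigma2, cfg,
                        epsilon %||% resolve_epsilon(cfg, y)), numeric(1)))
  mc_divergence_one(denoiser, y, sigma2, cfg,
                    epsilon %||% resolve_epsilon(cfg, y))
}

mc_divergence_one <- function(denoiser, y, sigma2, cfg, eps) {
  if (!identical(dim(y), dim(sigma2)))
    stop("sigma2 shape does not match y")
  fy <- denoiser(y)
  est <- 0
  for (k in seq_len(cfg$n_probes)) {
    b <- array(draw_probe(length(y), cfg$probe), dim(y))
    fp <- denoiser(y + eps * b)
    if (any(!is.finite(fp)) || any(!is.finite(fy)))
      stop("denoiser produced non-finite output (eps = ", signif(eps, 3), ")")
    est <- est + sum(b * sigma2 * (fp - fy)) / eps
  }
  est / cfg$n_probes
}

#' Exact divergence oracle for a linear denoiser
#'
#' For `f(y) = A y` the sigma^2-weighted divergence is
#' `sum_d sigma_d^2 A_dd`. Used as an independent oracle for the
#' Monte-Carlo estimator.
#'
#' @param A Square matrix acting on vectorised images.
#' @param sigma2 Vector of per-pixel noise variances, `length(sigma2) == nrow(A)`.
#' @return Scalar.
#' @export
analytic_divergence_linear <- function(A, sigma2) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("A must be square")
  if (length(sigma2) != nrow(A)) stop("sigma2 length must match nrow(A)")
  sum(diag(A) * as.numeric(sigma2))
}

#' Spatially variant SURE loss
#'
#' Observable estimate of the per-pixel mean squared error between the
#' denoiser output and the unknown clean image, for spatially variant
#' zero-mean Gaussian noise with known per-pixel standard deviation. For a
#' batch (list of images) the loss is the average of per-image losses, as
#' when averaging across diffusion directions.
#'
#' @param denoiser Function mapping a real matrix to a matrix of the same
#'   shape.
#' @param y Real matrix or list of matrices (batch).
#' @param noise_map Per-pixel noise standard deviation, same shape as `y`
#'   (non-negative).
#' @param cfg A [sure_config()].
#' @return Scalar SURE value.
#' @export
sure_loss <- function(denoiser, y, noise_map, cfg = sure_config()) {
  if (any(noise_map < 0)) stop("noise_map must be non-negative")
  if (all(noise_map == 0))
    warning("all-zero noise map: SURE reduces to the fidelity term")
  eps <- resolve_epsilon(cfg, y)
  if (!is.null(cfg$probe_seed)) set.seed(cfg$probe_seed)
  sigma2 <- noise_map^2
  one <- function(yi) {
    fy <- denoiser(yi)
    D <- length(yi)
    fid <- sum((fy - yi)^2)
    div <- mc_divergence_one(denoiser, yi, sigma2, cfg, eps)
    const <- if (cfg$include_constant) sum(sigma2) else 0
    (fid - const + 2 * div) / D
  }
  if (is.list(y)) mean(vapply(y, one, numeric(1))) else one(y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
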