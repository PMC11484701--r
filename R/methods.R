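# S3 methods for fitted denoisers.

#' @export
print.dwi_denoiser <- function(x, ...) {
  cat("Self-supervised DWI denoiser\n")
  cat("  strategy:", x$strategy, "\n")
  cfg <- x$net$config
  cat("  architecture:", cfg$family,
      if (cfg$family == "dncnn")
        sprintf("(depth %d, width %d)", cfg$depth, cfg$width)
      else
        sprintf("(%d levels, base width %d)", cfg$levels, cfg$width),
      "-", count_parameters(x$net), "parameters\n")
  cat("  input:", x$n_channels, "channel(s),", x$H, "x", x$W, "pixels,",
      length(x$samples), "samples\n")
  cat(sprintf("  trained %d epoch(s); best validation loss %.6g at epoch %d\n",
              nrow(x$history), x$best_val, x$best_epoch))
  invisible(x)
}

#' @export
summary.dwi_denoiser <- function(object, ...) {
  print(object)
  h <- object$history
  cat("\nLoss history (last entries):\n")
  print(utils::tail(h, 5L), row.names = FALSE)
  r <- residuals(object)
  cat(sprintf("\nCorrected residual on training samples: variance %.4f, mean %.4f (n = %d)\n",
              stats::var(r), mean(r), length(r)))
  invisible(object)
}

#' @export
coef.dwi_denoiser <- function(object, ...) flatten_params(object$net$params)

#' Predict (denoise) from a fitted denoiser
#'
#' With `newdata` a `dwi_prep` (or list of them), denoises the
#' full-repetition averaged direction images; with `newdata = NULL` the
#' training samples are denoised.
#'
#' @param object A `dwi_denoiser`.
#' @param newdata Optional `dwi_prep` or list of them.
#' @param ... Unused.
#' @return See [denoise()]; for `newdata = NULL`, a list of denoised
#'   training-sample images.
#' @export
predict.dwi_denoiser <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    sm <- denoise_samples(object, lapply(object$samples, function(s) {
      # training samples are stored normalized; undo for a uniform path
      s$target <- s$target * s$scale %||% 1
      if (!is.null(s$guidance)) s$guidance <- s$guidance * s$scale %||% 1
      if (!is.null(s$sigma)) s$sigma <- s$sigma * s$scale %||% 1
      s$scale <- NULL
      s
    }))
    return(lapply(sm, `[[`, "denoised"))
  }
  denoise(object, newdata)
}

#' Corrected residuals of a fitted denoiser
#'
#' Noise-map-corrected residuals `(noisy - denoised) / sigma` pooled over
#' the training samples (pixels where the noise map exceeds
#' `mask_threshold * max(sigma)`). Under ideal denoising these are standard
#' normal.
#'
#' @param object A `dwi_denoiser`.
#' @param mask_threshold Fraction of the maximum noise level below which
#'   pixels are excluded.
#' @param ... Unused.
#' @return Numeric vector of corrected residual values.
#' @export
residuals.dwi_denoiser <- function(object, mask_threshold = 0.05, ...) {
  sm <- denoise_samples(object, lapply(object$samples, function(s) {
    s$target <- s$target * s$scale %||% 1
    if (!is.null(s$guidance)) s$guidance <- s$guidance * s$scale %||% 1
    if (!is.null(s$sigma)) s$sigma <- s$sigma * s$scale %||% 1
    s$scale <- NULL
    s
  }))
  unlist(lapply(sm, function(s) {
    cr <- corrected_residual(s$target, s$denoised, s$sigma, mask_threshold)
    cr$residual[cr$mask]
  }))
}

#' Plot the training history of a fitted denoiser
#'
#' Training and validation loss per epoch.
#'
#' @param x A `dwi_denoiser`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.dwi_denoiser <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train, h$val), type = "l", lty = 1,
                    col = c("grey40", "firebrick"), xlab = "epoch",
                    ylab = paste(x$strategy, "loss"), ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}
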