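# S3 methods for fitted enhancement objects.

#' @export
print.eashe <- function(x, ...) {
  d <- dim(x$input)
  cat(sprintf("Entropy-based adaptive subhistogram equalization (%dx%d, %s)\n",
              d[1], d[2], if (n_channels(x$input) == 3L) "RGB" else "gray"))
  if (x$fallback) {
    cat("  degenerate input: identity mapping returned\n")
  } else {
    cat("  thresholds (ks1, ks2, ks3):", x$segmentation$thresholds, "\n")
    cat("  output ranges:", x$allocation$ranges, "\n")
    cat(sprintf("  control factors: alpha_low = %.4f, alpha_high = %.4f\n",
                x$side_stats$alpha_low, x$side_stats$alpha_high))
  }
  invisible(x)
}

#' Summarize an enhancement with its quality metrics
#'
#' @param object An \code{eashe} fit.
#' @param ... Unused.
#' @return A \code{summary.eashe} object bundling the fit diagnostics with a
#'   [quality_report()] of output against input.
#' @export
summary.eashe <- function(object, ...) {
  structure(
    list(fit = object, quality = quality_report(object$input, object$image)),
    class = "summary.eashe"
  )
}

#' @export
print.summary.eashe <- function(x, ...) {
  print(x$fit)
  print(x$quality)
  invisible(x)
}

#' Apply a fitted enhancement mapping to a new image
#'
#' Reuses the lookup table learned by [eashe()] on another image of the same
#' kind (e.g. the next frame of a sequence). Gray images go straight through
#' the LUT; RGB images are rescaled around their driving channel as in the
#' original fit.
#'
#' @param object An \code{eashe} fit.
#' @param newdata An 8-bit image; defaults to the training image.
#' @param ... Unused.
#' @return The remapped image.
#' @export
predict.eashe <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$image)
  check_image8(newdata)
  if (n_channels(newdata) == 1L) {
    apply_lut(newdata, object$lut)
  } else {
    driver <- switch(object$config$color_policy,
      luminance = {
        d <- round_half_away(
          (newdata[, , 1] + newdata[, , 2] + newdata[, , 3]) / 3)
        storage.mode(d) <- "integer"
        d
      },
      value_channel(newdata)
    )
    scale_rgb(newdata, driver, apply_lut(driver, object$lut))
  }
}

#' Diagnostic plot of an enhancement
#'
#' Two histograms (input and output intensity distributions) and the learned
#' level mapping.
#'
#' @param x An \code{eashe} fit.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.eashe <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  hin <- compute_histogram(x$input)$counts
  hout <- compute_histogram(x$image)$counts
  graphics::barplot(hin, names.arg = NULL, border = NA, space = 0,
                    main = "Input histogram", xlab = "level", ylab = "count",
                    ...)
  graphics::barplot(hout, names.arg = NULL, border = NA, space = 0,
                    main = "Output histogram", xlab = "level", ylab = "count",
                    ...)
  graphics::plot(0:255, x$lut, type = "s", main = "Level mapping",
                 xlab = "input level", ylab = "output level")
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
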