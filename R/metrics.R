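# Objective quality metrics: discrete entropy (detail richness), PSNR
# (deviation from the input / noise amplification) and AMBE (brightness
# preservation).

#' Discrete entropy of an image
#'
#' Shannon entropy in bits of the image's normalized intensity histogram,
#' \eqn{-\sum_k p_k \log_2 p_k}. Ranges from 0 (constant image) to 8,
#' attained only when all 256 levels are equiprobable. RGB images are scored
#' on the value channel.
#'
#' @param image 8-bit gray matrix or RGB array.
#' @return Entropy in bits, in \code{[0, 8]}.
#' @export
discrete_entropy <- function(image) {
  h <- compute_histogram(image)
  entropy_bits(to_pdf(h), 0L, 255L)
}

metric_values <- function(image) {
  check_image8(image)
  if (n_channels(image) == 3L) as.numeric(value_channel(image))
  else as.numeric(image)
}

check_same_dim <- function(x, y) {
  if (!identical(dim(x), dim(y))) {
    stop(input_error("images must have identical dimensions"))
  }
}

#' Mean squared error between two images
#'
#' @param x,y 8-bit images of identical dimensions.
#' @return Mean of squared per-pixel intensity differences.
#' @export
mse <- function(x, y) {
  vx <- metric_values(x); vy <- metric_values(y)
  check_same_dim(x, y)
  mean((vx - vy)^2)
}

#' Peak signal-to-noise ratio
#'
#' \eqn{\mathrm{PSNR} = 10 \log_{10}(255^2 / \mathrm{MSE})} in dB. Identical
#' images (MSE = 0) return \code{Inf}.
#'
#' @inheritParams mse
#' @return PSNR in dB (possibly \code{Inf}).
#' @export
psnr <- function(x, y) {
  m <- mse(x, y)
  if (m == 0) return(Inf)
  10 * log10(255^2 / m)
}

#' Absolute mean brightness error
#'
#' \eqn{|\bar X - \bar Y|}: the absolute difference of the two images' mean
#' intensities, in gray levels. Small values mean the enhancement preserved
#' overall brightness.
#'
#' @inheritParams mse
#' @return Non-negative brightness difference in gray levels.
#' @export
ambe <- function(x, y) {
  vx <- metric_values(x); vy <- metric_values(y)
  check_same_dim(x, y)
  abs(mean(vx) - mean(vy))
}

#' Quality report for an enhancement
#'
#' @param original,enhanced 8-bit images of identical dimensions.
#' @return An \code{eashe_quality} list with \code{de_input},
#'   \code{de_output} (bits), \code{psnr} (dB), \code{ambe} and \code{mse}.
#' @export
quality_report <- function(original, enhanced) {
  structure(
    list(
      de_input = discrete_entropy(original),
      de_output = discrete_entropy(enhanced),
      psnr = psnr(original, enhanced),
      ambe = ambe(original, enhanced),
      mse = mse(original, enhanced)
    ),
    class = "eashe_quality"
  )
}

#' @export
print.eashe_quality <- function(x, ...) {
  cat("Image quality report\n")
  cat(sprintf("  discrete entropy: %.4f -> %.4f bits\n",
              x$de_input, x$de_output))
  cat(sprintf("  PSNR: %s dB\n",
              if (is.infinite(x$psnr)) "inf" else sprintf("%.4f", x$psnr)))
  cat(sprintf("  AMBE: %.4f gray levels\n", x$ambe))
  invisible(x)
}

#' @export
as.data.frame.eashe_quality <- function(x, ...) {
  data.frame(de_input = x$de_input, de_output = x$de_output,
             psnr = x$psnr, ambe = x$ambe, mse = x$mse)
}

# Flat JSON-ready representation; infinite PSNR becomes the string "inf".
quality_flat <- function(report) {
  out <- unclass(report)
  if (is.infinite(out$psnr)) out$psnr <- "inf"
  out
}
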