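# Transfer functions and the full enhancement pipeline. Each output segment
# is equalized independently inside its allocated range; the per-level
# mapping is materialized as a single lookup table (LUT) applied per pixel.

#' Classical histogram-equalization transfer function
#'
#' The textbook mapping \eqn{f(k) = K_l + (K_u - K_l)\,\mathrm{cdf}(k)}
#' (rounded half away from zero), spreading the input over the full target
#' range. Used as the built-in baseline the adaptive method is compared to.
#'
#' @param pdf Length-256 density.
#' @param K_l,K_u Target output range, default the full \code{[0, 255]}.
#' @return Integer LUT of length 256 (monotone non-decreasing).
#' @export
classical_he_transfer <- function(pdf, K_l = 0L, K_u = 255L) {
  if (K_l > K_u) stop(input_error("K_l must not exceed K_u"))
  cdf <- cumsum(pdf)
  as.integer(round_half_away(K_l + (K_u - K_l) * cdf))
}

#' Per-segment equalization transfer
#'
#' Each output segment \code{[l_r, u_r]} is equalized with its own
#' segment-local CDF: with \eqn{C_r = c(u_r)} and \eqn{C_0 = 0}, levels in
#' segment \eqn{r} map through
#' \eqn{f(k) = l_r + (u_r - l_r)\,(c(k) - C_{r-1})/(C_r - C_{r-1})}, so every
#' segment's output spans exactly its allocated range and the union of the
#' independently equalized segments tiles \code{[0, 255]}. A segment with no
#' mass inherits a linear ramp so the LUT stays total and monotone.
#'
#' @param cdf Length-256 normalized CDF from [normalized_cdf()].
#' @param alloc An \code{eashe_allocation}.
#' @return Integer LUT of length 256.
#' @export
segment_transfer <- function(cdf, alloc) {
  stopifnot(inherits(alloc, "eashe_allocation"))
  f <- integer(256L)
  for (r in seq_len(alloc$n_subs)) {
    l_r <- alloc$out_bounds[r, "l"]
    u_r <- alloc$out_bounds[r, "u"]
    c_prev <- if (r == 1L) 0 else cdf[l_r]  # cdf at level l_r - 1
    c_r <- cdf[u_r + 1L]
    k <- l_r:u_r
    if (c_r > c_prev) {
      loc <- (cdf[k + 1L] - c_prev) / (c_r - c_prev)
    } else {
      loc <- (k - l_r) / max(u_r - l_r, 1L)
    }
    f[k + 1L] <- as.integer(round_half_away(l_r + (u_r - l_r) * loc))
  }
  f
}

#' Compose the remap and transfer into one total lookup table
#'
#' \code{final(k) = transfer(remap(k))} on levels inside the occupied input
#' range; levels outside it (where the remap is undefined) borrow the value
#' of the nearest defined level (lower neighbour on ties), keeping the LUT
#' total and monotone.
#'
#' @param remap Length-256 integer table from [remap_pdf()] (\code{NA} where
#'   undefined).
#' @param transfer Length-256 integer LUT.
#' @return Integer LUT of length 256.
#' @export
compose_lut <- function(remap, transfer) {
  final <- rep(NA_integer_, 256L)
  def <- which(!is.na(remap))
  if (length(def) == 0) stop(input_error("remap table is empty"))
  final[def] <- transfer[remap[def] + 1L]
  und <- which(is.na(final))
  if (length(und) > 0) {
    near <- vapply(und, function(i) {
      d <- abs(def - i)
      def[order(d, def)][1L]  # lower neighbour wins ties
    }, integer(1))
    final[und] <- final[near]
  }
  final
}

identity_lut <- function() 0:255

#' Apply a lookup table to an image
#'
#' @param image Gray matrix or RGB array of 8-bit intensities.
#' @param lut Integer LUT of length 256.
#' @return Image of the same shape with remapped intensities.
#' @export
apply_lut <- function(image, lut) {
  check_image8(image)
  out <- lut[as.integer(image) + 1L]
  dim(out) <- dim(image)
  out
}

#' Enhancement configuration
#'
#' @param color_policy How RGB images are handled: \code{"value_channel"}
#'   (default) enhances the per-pixel max of R, G, B and rescales the three
#'   channels proportionally, preserving hue; \code{"per_channel"} enhances
#'   each channel independently; \code{"luminance"} drives the scaling from
#'   the rounded channel mean instead of the max.
#' @param weight_hook Entropy-to-weight rule for the range allocation; see
#'   [allocate_ranges()].
#' @param emit_diagnostics Include thresholds, ranges and control factors in
#'   CLI reports.
#' @return An \code{eashe_config} list.
#' @export
eashe_config <- function(color_policy = c("value_channel", "per_channel",
                                          "luminance"),
                         weight_hook = c("reciprocal_clamped",
                                         "normalized_entropy", "uniform"),
                         emit_diagnostics = FALSE) {
  structure(
    list(
      color_policy = match.arg(color_policy),
      weight_hook = match.arg(weight_hook),
      emit_diagnostics = isTRUE(emit_diagnostics)
    ),
    class = "eashe_config"
  )
}

# Run the LUT-learning pipeline on a single-channel image; returns the LUT
# plus diagnostics, with the identity LUT on any degenerate stage.
eashe_fit_gray <- function(gray, config) {
  hist <- compute_histogram(gray, channel_policy = "value_channel")
  pdf <- to_pdf(hist)
  seg <- segment_histogram(pdf, hist$k_l, hist$k_u)
  fallback <- list(
    lut = identity_lut(), fallback = TRUE, histogram = hist,
    segmentation = seg, allocation = NULL, side_stats = NULL
  )
  if (seg$degenerate) return(fallback)
  tryCatch({
    alloc <- allocate_ranges(seg, weight_hook = config$weight_hook)
    adj <- remap_pdf(pdf, seg, alloc)
    stats <- side_stats(adj)
    p_mod <- adjust_pdf(adj, stats)
    cdf <- normalized_cdf(p_mod)
    transfer <- segment_transfer(cdf, alloc)
    lut <- compose_lut(adj$remap, transfer)
    list(lut = lut, fallback = FALSE, histogram = hist, segmentation = seg,
         allocation = alloc, adjusted = adj, side_stats = stats)
  }, eashe_degenerate = function(e) fallback)
}

# Rescale RGB channels so the driving channel (value or luminance) moves from
# old to new while hue is preserved; a zero driving value takes the new value
# on all channels.
scale_rgb <- function(image, old, new) {
  out <- image
  ratio <- ifelse(old > 0, new / old, 0)
  for (ch in 1:3) {
    v <- round_half_away(image[, , ch] * ratio)
    v[old == 0] <- new[old == 0]
    out[, , ch] <- clamp(v, 0, 255)
  }
  out
}

#' Entropy-based adaptive subhistogram equalization
#'
#' Enhances the contrast of an 8-bit image: the intensity histogram is split
#' into four entropy-balanced segments, each segment's output range is
#' reallocated by an entropy-weighted blend toward the uniform share, the
#' density is reshaped with a data-derived control factor, and each segment
#' is equalized independently within its own range. Degenerate inputs
#' (constant or two-level images, or any stage that cannot split) fall back
#' to the identity mapping with \code{fallback = TRUE}.
#'
#' @param image Integer matrix (gray) or H x W x 3 array (RGB) with values
#'   in \code{[0, 255]}.
#' @param config An [eashe_config()].
#' @return An object of class \code{eashe}: \code{image} (enhanced),
#'   \code{input}, \code{lut}, \code{fallback}, and the stage diagnostics
#'   (\code{segmentation}, \code{allocation}, \code{side_stats}).
#' @examples
#' img <- synth_image("gaussian_mixture", 64, 64, seed = 42)
#' fit <- eashe(img)
#' summary(fit)
#' @export
eashe <- function(image, config = eashe_config()) {
  check_image8(image)
  stopifnot(inherits(config, "eashe_config"))
  if (n_channels(image) == 1L) {
    fit <- eashe_fit_gray(image, config)
    enhanced <- apply_lut(image, fit$lut)
  } else if (config$color_policy == "per_channel") {
    luts <- vector("list", 3L)
    out <- image
    for (ch in 1:3) {
      f <- eashe_fit_gray(image[, , ch], config)
      luts[[ch]] <- f$lut
      out[, , ch] <- f$lut[image[, , ch] + 1L]
    }
    fit <- eashe_fit_gray(value_channel(image), config)
    fit$channel_luts <- luts
    enhanced <- out
  } else {
    driver <- switch(config$color_policy,
      value_channel = value_channel(image),
      luminance = round_half_away((image[, , 1] + image[, , 2] + image[, , 3]) / 3)
    )
    storage.mode(driver) <- "integer"
    fit <- eashe_fit_gray(driver, config)
    new_driver <- apply_lut(driver, fit$lut)
    enhanced <- scale_rgb(image, driver, new_driver)
  }
  structure(
    list(
      image = enhanced,
      input = image,
      lut = fit$lut,
      fallback = fit$fallback,
      histogram = fit$histogram,
      segmentation = fit$segmentation,
      allocation = fit$allocation,
      side_stats = fit$side_stats,
      config = config
    ),
    class = "eashe"
  )
}

#' Classical histogram equalization of an image
#'
#' Full-range global HE baseline: maps intensities through the cumulative
#' distribution onto \code{[0, 255]}. RGB images are handled with the same
#' color policy machinery as [eashe()].
#'
#' @inheritParams eashe
#' @return Enhanced image of the same shape.
#' @export
classical_he <- function(image, config = eashe_config()) {
  check_image8(image)
  if (n_channels(image) == 1L) {
    lut <- classical_he_transfer(to_pdf(compute_histogram(image)))
    apply_lut(image, lut)
  } else {
    driver <- value_channel(image)
    lut <- classical_he_transfer(to_pdf(compute_histogram(driver)))
    scale_rgb(image, driver, apply_lut(driver, lut))
  }
}
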