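# Output dynamic-range allocation: each of the four segments gets an output
# interval whose width blends its input span toward the uniform share L/4,
# weighted by (the reciprocal of) its entropy; the input density is then
# remapped onto the new intervals.

#' Allocate output dynamic ranges to the four segments
#'
#' For segment \eqn{r} with input span \eqn{span_r = m_r - m_{r-1}} and
#' entropy \eqn{E_r}, the blended width is
#' \deqn{aspan_r = span_r + w_r (L/N - span_r)}
#' with \eqn{w_r = \min(1/E_r, 1)} (and \eqn{w_r = 1} when \eqn{E_r = 0}):
#' low-entropy segments are pulled strongly toward the uniform share
#' \eqn{L/N = 64}, information-rich ones keep their span. Real widths are
#' normalized to \eqn{L - N = 252} interior levels and rounded by largest
#' remainder (minimum width 1, deficit taken from the largest), and output
#' bounds tile \code{[0, 255]} with \eqn{l_1 = 0},
#' \eqn{u_r = l_r + range_r}, \eqn{l_{r+1} = u_r + 1}.
#'
#' @param seg An \code{eashe_segmentation} (not degenerate).
#' @param total_levels Number of gray levels, 256 for 8-bit images.
#' @param weight_hook How segment entropy turns into the blend weight
#'   \eqn{w_r}: \code{"reciprocal_clamped"} (default, above),
#'   \code{"normalized_entropy"} (\eqn{w_r = 1 - E_r / \sum E}), or
#'   \code{"uniform"} (\eqn{w_r = 1}: every segment gets the uniform share).
#' @return An \code{eashe_allocation}: \code{spans}, \code{aspans},
#'   \code{ranges}, and \code{out_bounds} (4 x 2 matrix of \eqn{(l_r, u_r)}).
#' @export
allocate_ranges <- function(seg, total_levels = 256L,
                            weight_hook = c("reciprocal_clamped",
                                            "normalized_entropy",
                                            "uniform")) {
  weight_hook <- match.arg(weight_hook)
  stopifnot(inherits(seg, "eashe_segmentation"))
  if (seg$degenerate) stop(degenerate_error("degenerate segmentation"))
  if (total_levels != 256L) {
    stop(input_error("only 8-bit images (256 levels) are supported"))
  }
  n_subs <- 4L
  m <- seg$boundaries
  spans <- diff(m)
  e <- seg$segment_entropies
  w <- switch(weight_hook,
    reciprocal_clamped = ifelse(e <= 0, 1, clamp(1 / e, 0, 1)),
    normalized_entropy = if (sum(e) <= 0) rep(1, n_subs)
                         else clamp(1 - e / sum(e), 0, 1),
    uniform = rep(1, n_subs)
  )
  share <- total_levels / n_subs
  aspans <- spans + w * (share - spans)
  rho <- aspans / sum(aspans) * (total_levels - n_subs)
  ranges <- largest_remainder(rho, total_levels - n_subs, min_width = 1L)
  u <- cumsum(ranges + 1L) - 1L
  l <- c(0L, u[-n_subs] + 1L)
  structure(
    list(
      spans = as.integer(spans),
      aspans = aspans,
      weights = w,
      ranges = ranges,
      out_bounds = cbind(l = l, u = u),
      n_subs = n_subs
    ),
    class = "eashe_allocation"
  )
}

# Largest-remainder integerization of non-negative real widths rho to a fixed
# integer total, each part >= min_width. Ties broken by lower index; any
# deficit to reach the minimum is taken from the currently largest part.
largest_remainder <- function(rho, total, min_width = 1L) {
  n <- length(rho)
  fl <- floor(rho)
  rem <- as.integer(total - sum(fl))
  if (rem > 0) {
    frac <- rho - fl
    give <- order(-frac, seq_len(n))[seq_len(rem)]
    fl[give] <- fl[give] + 1
  }
  r <- as.integer(fl)
  while (any(r < min_width)) {
    need <- which(r < min_width)[1L]
    big <- order(-r, seq_len(n))[1L]
    r[big] <- r[big] - 1L
    r[need] <- r[need] + 1L
  }
  r
}

#' Remap a density onto the allocated output ranges
#'
#' Each input segment \code{[a_r, b_r]} is mapped affinely onto its output
#' interval \code{[l_r, u_r]}: level \eqn{k} goes to
#' \eqn{k' = \mathrm{round}(l_r + (k - a_r)/(b_r - a_r) \cdot range_r)}
#' (rounding half away from zero). Probability mass moves with the levels and
#' collisions sum, so total mass is conserved exactly; levels the remap never
#' produces keep zero mass.
#'
#' @param pdf Length-256 density.
#' @param seg The segmentation the allocation was computed from.
#' @param alloc An \code{eashe_allocation}.
#' @return An \code{eashe_adjusted_pdf}: \code{p_adj} (length-256 density),
#'   \code{remap} (length-256 integer table, \code{NA} outside the occupied
#'   input range) and \code{E_adj}, the entropy of \code{p_adj} in bits.
#' @export
remap_pdf <- function(pdf, seg, alloc) {
  stopifnot(inherits(alloc, "eashe_allocation"))
  if (seg$degenerate) stop(degenerate_error("degenerate segmentation"))
  segs <- segment_intervals(seg$boundaries)
  remap <- rep(NA_integer_, 256L)
  for (r in seq_len(alloc$n_subs)) {
    a <- segs[[r]][1]; b <- segs[[r]][2]
    if (b < a) next
    k <- a:b
    l_r <- alloc$out_bounds[r, "l"]
    remap[k + 1L] <- as.integer(round_half_away(
      l_r + (k - a) / max(b - a, 1L) * alloc$ranges[r]))
  }
  p_adj <- numeric(256L)
  occ <- which(pdf > 0) - 1L
  for (k in occ) {
    kp <- remap[k + 1L]
    p_adj[kp + 1L] <- p_adj[kp + 1L] + pdf[k + 1L]
  }
  structure(
    list(p_adj = p_adj, remap = remap, E_adj = entropy_bits(p_adj, 0L, 255L)),
    class = "eashe_adjusted_pdf"
  )
}
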