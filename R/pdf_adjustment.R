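# Adaptive reshaping of the range-adjusted density. The adjusted histogram is
# split once more at its half-entropy level; each side gets a control factor
# alpha derived from how far the split sits from the side means, and the
# density is pulled quadratically toward the side's midpoint value
# (pdf_max + pdf_min)/2. alpha = 1 keeps the extremes fixed (full HE
# behaviour); alpha = 0 flattens the side completely (near-linear stretch).

#' Half-entropy split of the adjusted density
#'
#' @param adj An \code{eashe_adjusted_pdf} from [remap_pdf()].
#' @return Split level \eqn{I_{ks}} in \code{[0, 254]}.
#' @export
split_adjusted <- function(adj) {
  stopifnot(inherits(adj, "eashe_adjusted_pdf"))
  if (adj$E_adj <= 0) stop(degenerate_error("adjusted density has zero entropy"))
  half_entropy_threshold(adj$p_adj, 0L, 255L)
}

#' Mean intensity of each side of the split
#'
#' Conditional means of the adjusted density over \code{[0, I_ks]} and
#' \code{[I_ks + 1, 255]}.
#'
#' @inheritParams split_adjusted
#' @param I_ks Split level.
#' @return Numeric \code{c(I_avgsub1, I_avgsub2)}.
#' @export
side_means <- function(adj, I_ks) {
  p <- adj$p_adj
  lo_idx <- seq_len(I_ks + 1L)
  k <- 0:255
  mass1 <- sum(p[lo_idx])
  mass2 <- sum(p[-lo_idx])
  if (mass1 <= 0 || mass2 <= 0) {
    stop(degenerate_error("a side of the split carries no probability mass"))
  }
  c(sum(k[lo_idx] * p[lo_idx]) / mass1,
    sum(k[-lo_idx] * p[-lo_idx]) / mass2)
}

#' Enhancement control factors
#'
#' \eqn{\alpha_{low} = (I_{ks} - I_{avg1})/(I_{avg2} - I_{avg1})} governs the
#' lower side, \eqn{\alpha_{high} = (I_{avg2} - I_{ks})/(I_{avg2} - I_{avg1})}
#' the upper; they sum to 1 before clamping to \code{[0, 1]}. A split close
#' to the lower side mean yields a small \eqn{\alpha_{low}} (strong
#' flattening) and vice versa, so the reshaping adapts to the brightness
#' distribution. If the two side means coincide both factors are set to 0.
#'
#' @param I_ks Split level.
#' @param I_avgsub1,I_avgsub2 Side means from [side_means()].
#' @return Numeric \code{c(alpha_low, alpha_high)} in \code{[0, 1]}.
#' @export
control_factor <- function(I_ks, I_avgsub1, I_avgsub2) {
  if (I_avgsub2 <= I_avgsub1) return(c(alpha_low = 0, alpha_high = 0))
  d <- I_avgsub2 - I_avgsub1
  c(alpha_low = clamp((I_ks - I_avgsub1) / d, 0, 1),
    alpha_high = clamp((I_avgsub2 - I_ks) / d, 0, 1))
}

#' Side statistics of the adjusted density
#'
#' Convenience wrapper running [split_adjusted()], [side_means()] and
#' [control_factor()] and collecting, per side, the extremes of the density
#' over its occupied bins and their midpoint \code{pdf_avgmm}.
#'
#' @inheritParams split_adjusted
#' @return An \code{eashe_side_stats} list: \code{I_ks}, \code{I_avgsub1},
#'   \code{I_avgsub2}, \code{alpha_low}, \code{alpha_high}, and a two-row
#'   \code{sides} data frame (\code{pdf_min}, \code{pdf_max},
#'   \code{pdf_avgmm} per side).
#' @export
side_stats <- function(adj) {
  I_ks <- split_adjusted(adj)
  means <- side_means(adj, I_ks)
  alpha <- control_factor(I_ks, means[1], means[2])
  p <- adj$p_adj
  side_of <- function(lo, hi) {
    occ <- p[(lo:hi) + 1L]
    occ <- occ[occ > 0]
    if (length(occ) == 0) {
      c(pdf_min = NA_real_, pdf_max = NA_real_, pdf_avgmm = NA_real_)
    } else {
      c(pdf_min = min(occ), pdf_max = max(occ),
        pdf_avgmm = (min(occ) + max(occ)) / 2)
    }
  }
  sides <- rbind(side_of(0L, I_ks), side_of(I_ks + 1L, 255L))
  structure(
    list(
      I_ks = I_ks,
      I_avgsub1 = means[1], I_avgsub2 = means[2],
      alpha_low = unname(alpha[1]), alpha_high = unname(alpha[2]),
      sides = sides
    ),
    class = "eashe_side_stats"
  )
}

#' Quadratic pull of the density toward each side's midpoint
#'
#' Over the occupied bins of each side, values below the side midpoint
#' \eqn{pdf_{avgmm}} become
#' \eqn{pdf_{avgmm} - \alpha (pdf_{avgmm} - p)^2 / (pdf_{avgmm} - pdf_{min})}
#' and values above become
#' \eqn{pdf_{avgmm} + \alpha (p - pdf_{avgmm})^2 / (pdf_{max} - pdf_{avgmm})}.
#' The side extremes are fixed points at \eqn{\alpha = 1}; at
#' \eqn{\alpha = 0} every occupied bin collapses to the midpoint. A side
#' whose occupied bins all share one value is copied unchanged. Empty input
#' bins stay empty: no mass is invented at levels absent from the image.
#'
#' @inheritParams split_adjusted
#' @param stats An \code{eashe_side_stats} for \code{adj}; the alpha fields
#'   may be overridden for diagnostics.
#' @return Length-256 vector of non-negative weights (not renormalized; see
#'   [normalized_cdf()]).
#' @export
adjust_pdf <- function(adj, stats) {
  stopifnot(inherits(stats, "eashe_side_stats"))
  p <- adj$p_adj
  p_mod <- p
  bounds <- list(c(0L, stats$I_ks), c(stats$I_ks + 1L, 255L))
  alphas <- c(stats$alpha_low, stats$alpha_high)
  for (s in 1:2) {
    lo <- bounds[[s]][1]; hi <- bounds[[s]][2]
    idx <- which(p[(lo:hi) + 1L] > 0) + lo  # occupied level indices (1-based)
    if (length(idx) == 0) next
    mn <- stats$sides[s, "pdf_min"]
    mx <- stats$sides[s, "pdf_max"]
    if (!is.finite(mn) || mx == mn) next
    avg <- stats$sides[s, "pdf_avgmm"]
    a <- alphas[s]
    pv <- p[idx]
    below <- pv < avg
    above <- pv > avg
    out <- pv
    out[below] <- avg - a * (avg - pv[below])^2 / (avg - mn)
    out[above] <- avg + a * (pv[above] - avg)^2 / (mx - avg)
    p_mod[idx] <- out
  }
  p_mod
}

#' Normalized cumulative distribution of the modified density
#'
#' The reshaped weights need not sum to 1; the cumulative sum is divided by
#' its final value so the CDF ends exactly at 1.
#'
#' @param p_mod Length-256 non-negative weights from [adjust_pdf()].
#' @return Length-256 non-decreasing vector with final entry 1.
#' @export
normalized_cdf <- function(p_mod) {
  if (any(p_mod < 0)) stop(input_error("modified density has negative weights"))
  cs <- cumsum(p_mod)
  tot <- cs[256L]
  if (tot <= 0) stop(degenerate_error("modified density has zero total weight"))
  cs / tot
}
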