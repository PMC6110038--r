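# Intensity histograms, probability densities, entropy, and the four-way
# entropy-balanced segmentation that drives the whole pipeline.
#
# Levels run 0..255; vectors of length 256 are indexed with level + 1.

#' Intensity histogram of an 8-bit image
#'
#' Counts pixels at each of the 256 intensity levels. For RGB images the
#' value channel (per-pixel maximum of R, G, B) is histogrammed, which keeps
#' hue untouched when the enhancement is later applied.
#'
#' @param image Integer matrix (gray) or H x W x 3 array (RGB) with values
#'   in \code{[0, 255]}.
#' @param channel_policy For RGB input, \code{"value_channel"} histograms the
#'   per-pixel max of the three channels. \code{"gray"} requires a
#'   single-channel image.
#' @return An object of class \code{eashe_histogram}: list with integer
#'   \code{counts} (length 256), \code{total} pixel count, and the occupied
#'   range bounds \code{k_l}, \code{k_u}.
#' @examples
#' h <- compute_histogram(matrix(c(0, 0, 255, 255), 2, 2))
#' h$counts[c(1, 256)]  # two pixels at level 0, two at 255
#' @export
compute_histogram <- function(image, channel_policy = c("value_channel", "gray")) {
  channel_policy <- match.arg(channel_policy)
  check_image8(image)
  if (n_channels(image) == 3L) {
    if (channel_policy == "gray") {
      stop(input_error(
        "channel_policy \"gray\" requires a single-channel image; use \"value_channel\" for RGB"))
    }
    v <- value_channel(image)
  } else {
    v <- image
  }
  counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
  occ <- which(counts > 0L)
  structure(
    list(
      counts = counts,
      total = sum(counts),
      k_l = occ[1L] - 1L,
      k_u = occ[length(occ)] - 1L
    ),
    class = "eashe_histogram"
  )
}

# Per-pixel max of R, G, B (the HSV value channel), as an integer matrix.
value_channel <- function(image) {
  pmax(image[, , 1L], image[, , 2L], image[, , 3L])
}

#' Normalize a histogram to a probability density
#'
#' @param hist An \code{eashe_histogram} from [compute_histogram()].
#' @return Numeric vector of length 256 summing to 1.
#' @export
to_pdf <- function(hist) {
  stopifnot(inherits(hist, "eashe_histogram"))
  if (hist$total <= 0) stop(input_error("histogram has zero total count"))
  hist$counts / hist$total
}

#' Shannon entropy of a density over a level interval
#'
#' Computes \eqn{-\sum_{k=lo}^{hi} p_k \log_2 p_k} with the convention
#' \eqn{0 \log 0 = 0}. Base 2 throughout, so results are in bits and the
#' 256-level uniform density scores 8.
#'
#' @param pdf Numeric vector of length 256 of non-negative masses.
#' @param lo,hi Inclusive level bounds in \code{[0, 255]}.
#' @return Entropy in bits (non-negative).
#' @export
entropy_bits <- function(pdf, lo = 0L, hi = 255L) {
  if (lo > hi) stop(input_error("lo must not exceed hi"))
  p <- pdf[(lo:hi) + 1L]
  p <- p[p > 0]
  if (length(p) == 0) return(0)
  -sum(p * log2(p))
}

# Per-bin entropy contributions e(k) = -p log2 p over the full 256 levels.
bin_entropy <- function(pdf) {
  e <- numeric(256L)
  pos <- pdf > 0
  e[pos] <- -pdf[pos] * log2(pdf[pos])
  e
}

#' Half-entropy split level of a density interval
#'
#' Finds the smallest level \eqn{k_s \in [lo, hi-1]} whose cumulative entropy
#' from \code{lo} reaches half the interval's total entropy, so the two parts
#' \code{[lo, k_s]} and \code{[k_s + 1, hi]} carry (as nearly as the discrete
#' bins allow) equal entropy. The equal-entropy condition rarely has an exact
#' integer solution; the first level meeting or exceeding the half mark is
#' taken, and the result is clamped to \code{hi - 1} so neither side is empty.
#'
#' @inheritParams entropy_bits
#' @return Integer level in \code{[lo, hi - 1]}.
#' @export
half_entropy_threshold <- function(pdf, lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (lo >= hi) stop(input_error("hi must exceed lo"))
  e_total <- entropy_bits(pdf, lo, hi)
  if (e_total <= 0) stop(degenerate_error("zero entropy on interval"))
  e <- bin_entropy(pdf)[(lo:hi) + 1L]
  cum <- cumsum(e)
  # tiny slack so an exactly-half cumulative sum is not missed to rounding
  hit <- which(cum >= e_total / 2 - 1e-12)
  ks <- lo + hit[1L] - 1L
  min(ks, hi - 1L)
}

#' Four-way entropy-balanced histogram segmentation
#'
#' Splits the occupied range \code{[k_l, k_u]} at the half-entropy level
#' \eqn{k_{s2}}, then splits each half the same way (\eqn{k_{s1}} over
#' \code{[k_l, k_s2]}, \eqn{k_{s3}} over \code{[k_s2 + 1, k_u]}), yielding
#' four contiguous segments of near-equal entropy. Degenerate inputs (a
#' single occupied level, or a zero-entropy half) set the \code{degenerate}
#' flag instead of raising, so callers can fall back to the identity mapping.
#'
#' @param pdf Numeric length-256 density.
#' @param k_l,k_u Occupied-range bounds (from [compute_histogram()]).
#' @return An \code{eashe_segmentation}: \code{thresholds} (ks1, ks2, ks3),
#'   \code{boundaries} (m0..m4), \code{segment_entropies} (bits) and the
#'   \code{degenerate} flag.
#' @export
segment_histogram <- function(pdf, k_l, k_u) {
  out <- structure(
    list(
      thresholds = rep(NA_integer_, 3L),
      boundaries = rep(NA_integer_, 5L),
      segment_entropies = rep(NA_real_, 4L),
      k_l = as.integer(k_l), k_u = as.integer(k_u),
      degenerate = TRUE
    ),
    class = "eashe_segmentation"
  )
  ks <- tryCatch(
    {
      ks2 <- half_entropy_threshold(pdf, k_l, k_u)
      ks1 <- half_entropy_threshold(pdf, k_l, ks2)
      ks3 <- half_entropy_threshold(pdf, ks2 + 1L, k_u)
      c(ks1, ks2, ks3)
    },
    eashe_degenerate = function(e) NULL,
    eashe_input_error = function(e) NULL
  )
  if (is.null(ks)) return(out)
  m <- c(k_l, ks, k_u)
  if (!(m[1] <= m[2] && m[2] < m[3] && m[3] < m[4] && m[4] <= m[5])) return(out)
  segs <- segment_intervals(m)
  out$thresholds <- as.integer(ks)
  out$boundaries <- as.integer(m)
  out$segment_entropies <- vapply(
    segs, function(ab) entropy_bits(pdf, ab[1], ab[2]), numeric(1))
  out$degenerate <- FALSE
  out
}

# Input intervals [m0,m1], [m1+1,m2], [m2+1,m3], [m3+1,m4] as a list of
# (lo, hi) pairs.
segment_intervals <- function(m) {
  list(
    c(m[1], m[2]),
    c(m[2] + 1L, m[3]),
    c(m[3] + 1L, m[4]),
    c(m[4] + 1L, m[5])
  )
}

#' @export
print.eashe_segmentation <- function(x, ...) {
  if (x$degenerate) {
    cat("Entropy-balanced segmentation: degenerate (identity fallback)\n")
  } else {
    cat("Entropy-balanced segmentation\n")
    cat("  thresholds (ks1, ks2, ks3):", x$thresholds, "\n")
    cat("  boundaries (m0..m4):      ", x$boundaries, "\n")
    cat("  segment entropies (bits): ",
        sprintf("%.4f", x$segment_entropies), "\n")
  }
  invisible(x)
}
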