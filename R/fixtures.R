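# Deterministic synthetic test images. The generators emulate the intensity
# regimes of typical photographic/microscopy test sets (bright-dominant,
# low-contrast narrow band, bimodal) so every code path runs without any
# external image; the same spec always yields a bit-identical image.

#' Generate a synthetic 8-bit test image
#'
#' @param kind One of:
#'   \describe{
#'     \item{constant}{every pixel at \code{level}.}
#'     \item{ramp}{row-wise linear sweep 0..255 across the width.}
#'     \item{uniform_exact}{every level appears exactly
#'       \code{height * width / 256} times (dimensions must make that an
#'       integer); the exactly uniform histogram.}
#'     \item{low_contrast}{seeded draws confined to the narrow band
#'       \code{band} (Gaussian around the band centre, clipped into the
#'       band).}
#'     \item{gaussian_mixture}{per-pixel draws from a seeded Gaussian
#'       mixture (\code{means}, \code{sigmas}, \code{weights}), rounded and
#'       clipped to \code{[0, 255]}; bimodal by default.}
#'     \item{spikes}{mass only at \code{levels}, in proportions
#'       \code{props}.}
#'   }
#' @param height,width Image dimensions (pixels).
#' @param seed Integer seed; the global RNG state is left untouched.
#' @param level Constant level for \code{kind = "constant"}.
#' @param band Inclusive \code{c(lo, hi)} band for \code{low_contrast}.
#' @param means,sigmas,weights Mixture parameters for
#'   \code{gaussian_mixture}.
#' @param levels,props Levels and proportions for \code{spikes}.
#' @return Integer matrix of intensities in \code{[0, 255]}.
#' @examples
#' img <- synth_image("gaussian_mixture", 64, 64, seed = 1)
#' range(img)
#' @export
synth_image <- function(kind = c("constant", "ramp", "uniform_exact",
                                 "low_contrast", "gaussian_mixture",
                                 "spikes"),
                        height, width, seed = 1L,
                        level = 128L,
                        band = c(100L, 139L),
                        means = c(60, 190), sigmas = c(10, 10),
                        weights = c(0.5, 0.5),
                        levels = NULL, props = NULL) {
  kind <- match.arg(kind)
  height <- as.integer(height); width <- as.integer(width)
  if (is.na(height) || is.na(width) || height < 1L || width < 1L) {
    stop(input_error("height and width must be positive integers"))
  }
  n <- height * width
  v <- switch(kind,
    constant = {
      if (level < 0 || level > 255) stop(input_error("level must be in [0, 255]"))
      rep(as.integer(level), n)
    },
    ramp = {
      col <- rep(seq_len(width) - 1L, each = height)
      if (width == 1L) rep(0L, n)
      else as.integer(round_half_away(col * 255 / (width - 1L)))
    },
    uniform_exact = {
      if (n %% 256L != 0L) {
        stop(input_error("height * width must be divisible by 256"))
      }
      per <- n %/% 256L
      vals <- rep(0:255, each = per)
      with_seed(seed, sample(vals))
    },
    low_contrast = {
      if (length(band) != 2L || band[1] > band[2] ||
          band[1] < 0 || band[2] > 255) {
        stop(input_error("band must be c(lo, hi) within [0, 255]"))
      }
      mid <- mean(band)
      sd <- max((band[2] - band[1]) / 4, 0.5)
      x <- with_seed(seed, stats::rnorm(n, mean = mid, sd = sd))
      as.integer(clamp(round_half_away(x), band[1], band[2]))
    },
    gaussian_mixture = {
      kcomp <- length(means)
      if (length(sigmas) != kcomp || length(weights) != kcomp ||
          any(weights < 0) || sum(weights) <= 0) {
        stop(input_error("means, sigmas and weights must have equal length and non-negative weights"))
      }
      w <- weights / sum(weights)
      x <- with_seed(seed, {
        z <- sample.int(kcomp, n, replace = TRUE, prob = w)
        stats::rnorm(n, mean = means[z], sd = sigmas[z])
      })
      as.integer(clamp(round_half_away(x), 0, 255))
    },
    spikes = {
      if (is.null(levels) || is.null(props) || length(levels) != length(props) ||
          any(levels < 0) || any(levels > 255) || any(props < 0) ||
          sum(props) <= 0) {
        stop(input_error("spikes needs matching levels in [0, 255] and non-negative props"))
      }
      pr <- props / sum(props)
      with_seed(seed,
        as.integer(sample(levels, n, replace = TRUE, prob = pr)))
    }
  )
  matrix(v, nrow = height, ncol = width)
}

#' Seeded random probability density over the 256 levels
#'
#' Positive mass on `occupied` distinct seeded levels, normalized to 1.
#' Used as the input for oracle tests of the segmentation machinery.
#'
#' @param seed Integer seed.
#' @param occupied Number of occupied levels, 1..256.
#' @return Length-256 density summing to 1.
#' @export
random_pdf <- function(seed, occupied = 64L) {
  occupied <- as.integer(occupied)
  if (occupied < 1L || occupied > 256L) {
    stop(input_error("occupied must be in [1, 256]"))
  }
  with_seed(seed, {
    lev <- sample(0:255, occupied)
    mass <- stats::runif(occupied, min = 0.05, max = 1)
    p <- numeric(256L)
    p[lev + 1L] <- mass / sum(mass)
    p
  })
}
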