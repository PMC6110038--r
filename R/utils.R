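# Internal helpers shared across the pipeline.

# Round half away from zero (bit-exact across platforms, unlike base round()
# which rounds half to even).
round_half_away <- function(x) trunc(x + 0.5 * sign(x))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Degenerate-input condition: stages signal it, enhance() catches it and falls
# back to the identity mapping.
degenerate_error <- function(msg) {
  structure(
    class = c("eashe_degenerate", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
}

input_error <- function(msg) {
  structure(
    class = c("eashe_input_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
}

# Run code with a private RNG stream: the global .Random.seed is restored
# afterwards so generators never perturb user randomness.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Validate an 8-bit image: integer-valued matrix (gray) or H x W x 3 array
# (RGB), every value in [0, 255]. Returns the image with storage mode double
# kept as-is; callers index with value + 1.
check_image8 <- function(image, arg = "image") {
  if (is.null(image) || length(image) == 0) {
    stop(input_error(sprintf("%s is empty", arg)))
  }
  d <- dim(image)
  ok_gray <- is.matrix(image)
  ok_rgb <- is.array(image) && length(d) == 3 && d[3] == 3
  if (!ok_gray && !ok_rgb) {
    stop(input_error(sprintf(
      "%s must be a matrix (gray) or an H x W x 3 array (RGB)", arg)))
  }
  v <- as.vector(image)
  if (anyNA(v) || any(v < 0) || any(v > 255) || any(v != floor(v))) {
    stop(input_error(sprintf(
      "%s must contain integer intensities in [0, 255]", arg)))
  }
  image
}

n_channels <- function(image) {
  if (is.matrix(image)) 1L else dim(image)[3]
}
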