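# Image readers and writers. PNG and TIFF go through the png and tiff
# packages; PGM/PPM (netpbm P2/P3/P5/P6) have no installed R reader and are
# parsed here directly. Only 8-bit data is accepted.

#' Read an 8-bit image
#'
#' Supports PNG, TIFF, PGM and PPM. Gray images come back as an integer
#' matrix, color images as an H x W x 3 array (an alpha channel, if present,
#' is dropped). Inputs with more than 8 bits per sample are rejected.
#'
#' @param path Path to the image file.
#' @return 8-bit image (matrix or H x W x 3 array).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop(input_error(sprintf("file not found: %s", path)))
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = read_png8(path),
    tif = ,
    tiff = read_tiff8(path),
    pgm = ,
    ppm = ,
    pnm = read_pnm8(path),
    stop(input_error(sprintf(
      "unsupported format '.%s' (supported: png, tiff, pgm, ppm)", ext)))
  )
  check_image8(img, arg = path)
}

read_png8 <- function(path) {
  raw <- png::readPNG(path, info = TRUE)
  info <- attr(raw, "info")
  if (!is.null(info$bit.depth) && info$bit.depth > 8) {
    stop(input_error(sprintf(
      "%s: %d-bit PNG not supported; only 8-bit images are accepted",
      path, info$bit.depth)))
  }
  from_unit(raw)
}

read_tiff8 <- function(path) {
  raw <- tiff::readTIFF(path, info = TRUE)
  bits <- attr(raw, "bits.per.sample")
  if (!is.null(bits) && any(bits > 8)) {
    stop(input_error(sprintf(
      "%s: %d-bit TIFF not supported; only 8-bit images are accepted",
      path, max(bits))))
  }
  from_unit(raw)
}

# [0,1] arrays from png/tiff -> integer 0..255; drop alpha.
from_unit <- function(raw) {
  x <- round_half_away(raw * 255)
  d <- dim(x)
  if (length(d) == 3) {
    if (d[3] == 1) {
      x <- x[, , 1]
    } else if (d[3] >= 3) {
      x <- x[, , 1:3]
    } else {
      stop(input_error("two-channel images are not supported"))
    }
  }
  dm <- dim(x)
  x <- as.integer(x)  # drops reader metadata attributes
  dim(x) <- dm
  x
}

read_pnm8 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  data <- readBin(con, "raw", n = file.size(path))
  # header: magic, width, height, maxval -- whitespace separated, '#' comments
  pos <- 1L
  next_token <- function() {
    repeat {
      while (pos <= length(data) &&
             data[pos] %in% as.raw(c(0x20, 0x09, 0x0a, 0x0d))) pos <<- pos + 1L
      if (pos <= length(data) && data[pos] == as.raw(0x23)) {  # '#'
        while (pos <= length(data) && data[pos] != as.raw(0x0a)) pos <<- pos + 1L
      } else break
    }
    start <- pos
    while (pos <= length(data) &&
           !(data[pos] %in% as.raw(c(0x20, 0x09, 0x0a, 0x0d)))) pos <<- pos + 1L
    if (start >= pos) stop(input_error(sprintf("%s: truncated PNM header", path)))
    rawToChar(data[start:(pos - 1L)])
  }
  magic <- next_token()
  if (!magic %in% c("P2", "P3", "P5", "P6")) {
    stop(input_error(sprintf(
      "%s: unsupported PNM magic '%s' (supported: P2, P3, P5, P6)",
      path, magic)))
  }
  width <- as.integer(next_token())
  height <- as.integer(next_token())
  maxval <- as.integer(next_token())
  if (is.na(width) || is.na(height) || is.na(maxval) ||
      width < 1L || height < 1L) {
    stop(input_error(sprintf("%s: malformed PNM header", path)))
  }
  if (maxval > 255L) {
    stop(input_error(sprintf(
      "%s: maxval %d exceeds 255; only 8-bit images are accepted",
      path, maxval)))
  }
  channels <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- width * height * channels
  if (magic %in% c("P5", "P6")) {
    pos <- pos + 1L  # single whitespace byte after maxval
    if (pos + n - 1L > length(data)) {
      stop(input_error(sprintf("%s: truncated PNM pixel data", path)))
    }
    vals <- as.integer(data[pos:(pos + n - 1L)])
  } else {
    txt <- rawToChar(data[pos:length(data)])
    vals <- suppressWarnings(as.integer(strsplit(trimws(txt), "\\s+")[[1]]))
    if (length(vals) < n || anyNA(vals[seq_len(n)])) {
      stop(input_error(sprintf("%s: truncated PNM pixel data", path)))
    }
    vals <- vals[seq_len(n)]
  }
  if (channels == 1L) {
    matrix(vals, nrow = height, ncol = width, byrow = TRUE)
  } else {
    # interleaved RGB triplets, row-major
    arr <- array(0L, dim = c(height, width, 3L))
    for (ch in 1:3) {
      arr[, , ch] <- matrix(vals[seq(ch, n, by = 3L)],
                            nrow = height, ncol = width, byrow = TRUE)
    }
    arr
  }
}

#' Write an 8-bit image
#'
#' Format chosen from the file extension: PNG, TIFF, or binary PGM (P5) /
#' PPM (P6) with maxval 255.
#'
#' @param image 8-bit image (matrix or H x W x 3 array).
#' @param path Destination path.
#' @return \code{path}, invisibly.
#' @export
write_image <- function(image, path) {
  check_image8(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(image / 255, target = path),
    tif = ,
    tiff = tiff::writeTIFF(image / 255, where = path, bits.per.sample = 8L),
    pgm = ,
    ppm = write_pnm(image, path),
    stop(input_error(sprintf(
      "unsupported output format '.%s' (supported: png, tiff, pgm, ppm)",
      ext)))
  )
  invisible(path)
}

write_pnm <- function(image, path) {
  gray <- n_channels(image) == 1L
  d <- dim(image)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("%s\n%d %d\n255\n", if (gray) "P5" else "P6", d[2], d[1]),
            con, eos = NULL)
  if (gray) {
    vals <- as.integer(t(image))  # row-major
  } else {
    vals <- as.integer(aperm(image, c(3, 2, 1)))  # RGB interleaved, row-major
  }
  writeBin(as.raw(vals), con)
  invisible(path)
}
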