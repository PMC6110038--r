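test_that("classical HE transfer follows the CDF", {
  uni <- rep(1 / 256, 256)
  f <- classical_he_transfer(uni, 0, 255)
  expect_true(all(abs(f - 0:255) <= 1))
  expect_false(is.unsorted(f))

  spike <- numeric(256); spike[1] <- 1
  expect_equal(classical_he_transfer(spike, 0, 255)[1], 255L)

  p <- numeric(256); p[c(1, 129)] <- c(0.25, 0.75)
  f2 <- classical_he_transfer(p, 0, 255)
  expect_equal(f2[1], 64L)    # round(255 * 0.25)
  expect_equal(f2[129], 255L)

  expect_error(classical_he_transfer(uni, 10, 5), class = "eashe_input_error")
})

test_that("segment transfer keeps every segment inside its range", {
  uni_seg <- segment_histogram(rep(1 / 256, 256), 0, 255)
  al <- allocate_ranges(uni_seg)

  # linear cdf -> near-identity per segment
  f <- segment_transfer((1:256) / 256, al)
  expect_true(all(abs(f - 0:255) <= 1))

  # all of segment 2's mass at its first level: local cdf saturates at once
  w <- numeric(256); w[c(1, 65, 129, 193)] <- 0.25
  cdf <- normalized_cdf(w)
  f2 <- segment_transfer(cdf, al)
  expect_true(all(f2[66:128] == 127L))

  for (seed in 1:25) {
    cdf <- normalized_cdf(rich_pdf(seed))
    fr <- segment_transfer(cdf, al)
    expect_false(is.unsorted(fr))
    expect_equal(fr[256], 255L)
    for (r in 1:4) {
      k <- al$out_bounds[r, "l"]:al$out_bounds[r, "u"]
      expect_true(all(fr[k + 1] >= al$out_bounds[r, "l"]))
      expect_true(all(fr[k + 1] <= al$out_bounds[r, "u"]))
    }
  }
})

test_that("LUT composition is total, monotone and fills gaps from neighbours", {
  expect_equal(compose_lut(0:255, 0:255), 0:255)

  remap <- rep(NA_integer_, 256)
  remap[c(101, 121)] <- c(0L, 63L)
  transfer <- 0:255; transfer[64] <- 255L; transfer[1] <- 0L
  final <- compose_lut(remap, transfer)
  expect_equal(final[101], 0L)
  expect_equal(final[121], 255L)
  # outside the occupied range: nearest defined neighbour
  expect_true(all(final[1:100] == 0L))
  expect_true(all(final[122:256] == 255L))

  for (seed in 1:25) {
    p <- rich_pdf(seed)
    occ <- which(p > 0) - 1
    seg <- segment_histogram(p, min(occ), max(occ))
    al <- allocate_ranges(seg)
    adj <- remap_pdf(p, seg, al)
    st <- side_stats(adj)
    cdf <- normalized_cdf(adjust_pdf(adj, st))
    final <- compose_lut(adj$remap, segment_transfer(cdf, al))
    expect_false(is.unsorted(final))
    expect_true(all(final >= 0 & final <= 255))
  }
})

test_that("enhancement of the exactly uniform image is near-identity", {
  img <- synth_image("uniform_exact", 16, 16, seed = 3)
  fit <- eashe(img)
  expect_false(fit$fallback)
  expect_equal(fit$segmentation$thresholds, c(63L, 127L, 191L))
  expect_equal(fit$allocation$ranges, rep(63L, 4))
  expect_true(all(abs(fit$image - img) <= 1))
})

test_that("degenerate images round-trip unchanged with the fallback flag", {
  for (img in list(synth_image("constant", 8, 8, level = 0),
                   synth_image("constant", 8, 8, level = 200),
                   synth_image("spikes", 8, 8, seed = 2,
                               levels = c(40, 220), props = c(0.5, 0.5)))) {
    fit <- expect_no_error(eashe(img))
    expect_true(fit$fallback)
    expect_identical(fit$image, fit$input)
    expect_equal(fit$lut, 0:255)
  }
  expect_error(eashe(matrix(numeric(0), 0, 0)), class = "eashe_input_error")
})

test_that("non-degenerate enhancements reach level 255 and stay in range", {
  for (seed in 1:10) {
    img <- synth_image("gaussian_mixture", 48, 48, seed = seed)
    fit <- eashe(img)
    expect_false(fit$fallback)
    expect_equal(max(fit$image), 255L)
    expect_true(all(fit$image >= 0 & fit$image <= 255))
    expect_identical(dim(fit$image), dim(img))
    expect_false(is.unsorted(fit$lut))
  }
})

test_that("RGB enhancement preserves shape and channel order relations", {
  gray <- synth_image("gaussian_mixture", 32, 32, seed = 11)
  arr <- array(0L, dim = c(32, 32, 3))
  arr[, , 1] <- gray
  arr[, , 2] <- as.integer(pmax(gray - 30L, 0L))
  arr[, , 3] <- as.integer(pmax(gray - 60L, 0L))
  fit <- eashe(arr)
  expect_identical(dim(fit$image), dim(arr))
  expect_true(all(fit$image >= 0 & fit$image <= 255))
  # value channel of the output equals the enhanced driving channel
  v_in <- pmax(arr[, , 1], arr[, , 2], arr[, , 3])
  expect_lte(max(abs(pmax(fit$image[, , 1], fit$image[, , 2], fit$image[, , 3]) -
                     fit$lut[v_in + 1])), 1)

  fit_pc <- eashe(arr, eashe_config(color_policy = "per_channel"))
  expect_identical(dim(fit_pc$image), dim(arr))
  fit_lum <- eashe(arr, eashe_config(color_policy = "luminance"))
  expect_identical(dim(fit_lum$image), dim(arr))
})

test_that("predict applies the learned LUT to new images", {
  img <- synth_image("gaussian_mixture", 32, 32, seed = 5)
  fit <- eashe(img)
  expect_identical(predict(fit), fit$image)
  img2 <- synth_image("gaussian_mixture", 32, 32, seed = 6)
  expect_identical(predict(fit, img2), apply_lut(img2, fit$lut))
})
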