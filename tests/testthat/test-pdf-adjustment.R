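# Build an adjusted-pdf object directly from a density (identity remap) so
# the reshaping stage can be tested in isolation.
adj_of <- function(p) {
  structure(list(p_adj = p, remap = 0:255, E_adj = entropy_bits(p, 0, 255)),
            class = "eashe_adjusted_pdf")
}

test_that("the adjusted-density split reuses the half-entropy rule", {
  expect_equal(split_adjusted(adj_of(rep(1 / 256, 256))), 127)
  p <- numeric(256); p[c(1, 256)] <- 0.5
  expect_equal(split_adjusted(adj_of(p)), 0)
  for (seed in 1:25) {
    q <- rich_pdf(seed)
    expect_identical(split_adjusted(adj_of(q)), oracle_half_entropy(q, 0, 255))
  }
  spike <- numeric(256); spike[5] <- 1
  expect_error(split_adjusted(adj_of(spike)), class = "eashe_degenerate")
})

test_that("side means are the conditional means of each half", {
  p <- numeric(256); p[c(1, 256)] <- 0.5
  expect_equal(side_means(adj_of(p), 0), c(0, 255))

  expect_equal(side_means(adj_of(rep(1 / 256, 256)), 127), c(63.5, 191.5))

  q <- numeric(256); q[c(11, 21, 201)] <- c(0.25, 0.25, 0.5)
  ks <- split_adjusted(adj_of(q))
  lo <- 0:ks; hi <- (ks + 1):255
  expected <- c(sum(lo * q[lo + 1]) / sum(q[lo + 1]),
                sum(hi * q[hi + 1]) / sum(q[hi + 1]))
  expect_equal(side_means(adj_of(q), ks), expected)

  expect_error(side_means(adj_of(q), 5), class = "eashe_degenerate")
})

test_that("control factors are complementary and clamped", {
  expect_equal(unname(control_factor(0, 0, 255)), c(0, 1))
  expect_equal(unname(control_factor(127, 63.5, 191.5)),
               c(63.5 / 128, 64.5 / 128))
  a <- control_factor(127, 63.5, 191.5)
  expect_equal(unname(a[1] + a[2]), 1)
  # symmetric split equidistant from both means
  expect_equal(unname(control_factor(100, 50, 150)), c(0.5, 0.5))
  # coincident means: no reshaping
  expect_equal(unname(control_factor(100, 80, 80)), c(0, 0))
})

test_that("alpha duality holds across seeded densities", {
  for (seed in 1:25) {
    st <- side_stats(adj_of(rich_pdf(seed)))
    expect_gte(st$alpha_low, 0); expect_lte(st$alpha_low, 1)
    expect_gte(st$alpha_high, 0); expect_lte(st$alpha_high, 1)
    expect_equal(st$alpha_low + st$alpha_high, 1, tolerance = 1e-12)
    expect_lte(st$I_avgsub1, st$I_ks)
    expect_lt(st$I_ks, st$I_avgsub2)
  }
})

test_that("quadratic reshaping has the stated algebraic fixed points", {
  # lower side occupies {11, 31, 51}, upper side {171, 191, 231}; the split
  # level and per-side stats are fixed by hand so the algebra is isolated
  p <- numeric(256)
  p[c(11, 31, 51, 171, 191, 231) + 1] <- c(0.01, 0.02, 0.05, 0.30, 0.12, 0.50)
  adj <- adj_of(p)
  mk_stats <- function(alpha_low, alpha_high) {
    structure(
      list(I_ks = 127L, I_avgsub1 = 38.75, I_avgsub2 = 210.65,
           alpha_low = alpha_low, alpha_high = alpha_high,
           sides = rbind(c(pdf_min = 0.01, pdf_max = 0.05, pdf_avgmm = 0.03),
                         c(pdf_min = 0.12, pdf_max = 0.50, pdf_avgmm = 0.31))),
      class = "eashe_side_stats")
  }

  # alpha = 1: per-side extremes are fixed points
  m1 <- adjust_pdf(adj, mk_stats(1, 1))
  expect_equal(m1[11 + 1], 0.01, tolerance = 1e-15)
  expect_equal(m1[51 + 1], 0.05, tolerance = 1e-15)
  expect_equal(m1[191 + 1], 0.12, tolerance = 1e-15)
  expect_equal(m1[231 + 1], 0.50, tolerance = 1e-15)

  # alpha = 0: every occupied bin collapses to its side midpoint
  m0 <- adjust_pdf(adj, mk_stats(0, 0))
  expect_equal(unname(m0[c(11, 31, 51) + 1]), rep(0.03, 3))
  expect_equal(unname(m0[c(171, 191, 231) + 1]), rep(0.31, 3))
  expect_true(all(m0[p == 0] == 0))

  # worked value: avgmm 0.03, alpha 0.5 at p = 0.02 gives
  # 0.03 - 0.5 * (0.01)^2 / 0.02 = 0.0275
  m5 <- adjust_pdf(adj, mk_stats(0.5, 0.5))
  expect_equal(unname(m5[31 + 1]), 0.0275)
})

test_that("reshaping never overshoots the side extremes or midpoint", {
  for (seed in 1:25) {
    p <- rich_pdf(seed)
    adj <- adj_of(p)
    st <- side_stats(adj)
    m <- adjust_pdf(adj, st)
    expect_true(all(m[p == 0] == 0))  # no mass invented at empty levels
    for (s in 1:2) {
      side <- if (s == 1) 0:st$I_ks else (st$I_ks + 1):255
      occ <- side[p[side + 1] > 0]
      if (length(occ) == 0) next
      avg <- st$sides[s, "pdf_avgmm"]
      expect_true(all(m[occ + 1] >= st$sides[s, "pdf_min"] - 1e-15))
      expect_true(all(m[occ + 1] <= st$sides[s, "pdf_max"] + 1e-15))
      # every value lies between its input and the midpoint
      expect_true(all(
        (m[occ + 1] - p[occ + 1]) * (avg - p[occ + 1]) >= -1e-15))
      # monotone in p for a fixed side
      ord <- occ[order(p[occ + 1])]
      expect_false(is.unsorted(m[ord + 1]))
    }
  }
})

test_that("the normalized CDF is a proper non-decreasing CDF ending at 1", {
  m <- numeric(256); m[1] <- 1
  expect_equal(normalized_cdf(m), rep(1, 256))

  expect_equal(normalized_cdf(rep(1 / 256, 256)), (1:256) / 256)

  for (seed in 1:20) {
    w <- rich_pdf(seed) * (1 + seed / 10)  # unnormalized weights
    cdf <- normalized_cdf(w)
    expect_equal(cdf, cumsum(w) / sum(w), tolerance = 1e-12)
    expect_false(is.unsorted(cdf))
    expect_equal(cdf[256], 1)
  }
  expect_error(normalized_cdf(numeric(256)), class = "eashe_degenerate")
})
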