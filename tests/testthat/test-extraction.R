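test_that("window masking zeroes the outside and keeps the inside", {
  set.seed(3)
  v <- matrix(rnorm(1024), 32, 32)
  m <- ev_map(v)
  # radius covering the whole image: identity on values
  big <- apply_window_mask(m, c(15.5, 15.5), 100)
  expect_equal(big$values, v)
  expect_true(all(big$mask))
  # fractional center with radius 0: no pixel centers inside
  expect_warning(z0 <- apply_window_mask(m, c(10.5, 10.5), 0), "no pixels")
  expect_equal(z0$values, matrix(0, 32, 32))
  # center on a pixel with radius 0: exactly that pixel survives (<= rule)
  one <- apply_window_mask(m, c(10, 10), 0)
  expect_identical(sum(one$mask), 1L)
  expect_equal(one$values[11, 11], v[11, 11])
  expect_error(apply_window_mask(m, c(200, 200), 5), "outside")
})

test_that("circular masks match the brute-force distance test", {
  set.seed(13)
  for (rep in 1:10) {
    ctr <- runif(2, 0, 31)
    r <- runif(1, 1, 20)
    expect_identical(circle_mask(c(32, 32), ctr, r),
                     oracle_circle(c(32, 32), ctr, r))
  }
  # boundary: pixel at distance exactly r is inside
  m <- circle_mask(c(9, 9), c(4, 4), 2)
  expect_true(m[5, 7])   # (4, 6): distance exactly 2
  expect_false(m[5, 8])
})

test_that("z-scores use the sample sd and are affine invariant", {
  m <- ev_map(matrix(c(-1, 1), 1, 2))
  z <- zscore_map(m)
  expect_equal(z, matrix(c(-1, 1) / sqrt(2), 1, 2), tolerance = 1e-12)
  set.seed(19)
  v <- matrix(rnorm(256), 16, 16)
  z1 <- zscore_map(ev_map(v))
  z2 <- zscore_map(ev_map(3 * v + 17))
  expect_equal(z1, z2, tolerance = 1e-9)
  expect_error(zscore_map(ev_map(matrix(5, 4, 4))), "variance")
})

test_that("the two z-scoring conventions differ only via the zeroed surround", {
  set.seed(23)
  v <- matrix(rnorm(1024, 0, 1e-3), 32, 32)
  m <- apply_window_mask(ev_map(v), c(15.5, 15.5), 10)
  z_all <- zscore_map(m, in_mask_only = FALSE)
  z_in <- zscore_map(m, in_mask_only = TRUE)
  expect_identical(unique(z_in[!m$mask]), 0)
  # in-mask-only stats computed from in-window pixels alone
  vi <- m$values[m$mask]
  expect_equal(z_in[m$mask], (vi - mean(vi)) / sd(vi), tolerance = 1e-12)
  # whole-image stats include the zeros, deflating the sd
  expect_lt(sd(m$values), sd(vi))
  expect_equal(z_all, (m$values - mean(m$values)) / sd(m$values),
               tolerance = 1e-12)
  # without a mask both conventions coincide
  m2 <- ev_map(v)
  expect_equal(zscore_map(m2, TRUE), zscore_map(m2, FALSE))
})

test_that("z-score thresholding marks outlier pixels and records the cutoff", {
  set.seed(31)
  v <- matrix(rnorm(1024, 0, 1e-4), 32, 32)
  v[12, 20] <- min(v) * 8            # one strongly negative pixel
  m <- ev_map(v)
  b <- threshold_map(m, threshold_spec(z_cut = -3))
  expect_identical(which(b$mask), which(v == v[12, 20]))
  expect_lt(b$threshold_record$cutoff_drr, 0)
  # realized cutoff is in delta-R/R units: mu + z_cut * sd
  expect_equal(b$threshold_record$cutoff_drr, mean(v) - 3 * sd(v))
  # an infinitely strict cut gives an empty map
  b0 <- threshold_map(m, threshold_spec(z_cut = -Inf))
  expect_identical(sum(b0$mask), 0L)
  # binarization is invariant to affine rescaling of the map
  b2 <- threshold_map(ev_map(0.5 * v + 2e-3), threshold_spec(z_cut = -3))
  expect_identical(b$mask, b2$mask)
})

test_that("percent-of-peak thresholding works on signal magnitude", {
  m <- ev_map(matrix(c(-4, -2, -1, 0), 2, 2))
  b <- threshold_map(m, threshold_spec("percent_max", percent = 0.5))
  expect_identical(b$mask, matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  expect_equal(b$threshold_record$cutoff_drr, -2)
  expect_error(threshold_map(ev_map(matrix(c(0, 1, 2, 3), 2, 2)),
                             threshold_spec("percent_max")),
               "no negative")
  expect_error(threshold_spec("percent_max", percent = 1.5), "percent")
  expect_error(threshold_spec(z_cut = 1), "negative")
})

test_that("binary pixels never appear outside the window mask", {
  set.seed(37)
  v <- matrix(rnorm(1024, 0, 1e-4), 32, 32)
  m <- apply_window_mask(ev_map(v), c(15.5, 15.5), 8)
  for (spec in list(threshold_spec(z_cut = -0.1),
                    threshold_spec("percent_max", percent = 0.01))) {
    b <- threshold_map(m, spec)
    expect_false(any(b$mask & !m$mask))
    expect_false(any(clean_map(b)$mask & !m$mask))
  }
})

test_that("3x3 median cleaning is a majority vote with FALSE padding", {
  # isolated pixel removed
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  expect_false(any(clean_map(bin_map(m))$mask))
  # all-false stays all-false
  expect_false(any(clean_map(bin_map(matrix(FALSE, 5, 5)))$mask))
  # solid 5x5 block: compare against the brute-force 9-neighborhood count
  m2 <- matrix(FALSE, 9, 9); m2[3:7, 3:7] <- TRUE
  got <- clean_map(bin_map(m2))$mask
  expect_identical(got, oracle_median3(m2))
  # corners of the block (3 of 9 neighbors) are removed, interior survives
  expect_false(got[3, 3]); expect_true(got[5, 5])
  # idempotent on the cleaned result of a large solid region
  expect_identical(clean_map(clean_map(bin_map(m2)))$mask, got)
})

test_that("median cleaning matches the brute-force oracle on random maps", {
  set.seed(43)
  for (rep in 1:10) {
    m <- matrix(runif(32 * 32) < 0.4, 32, 32)
    expect_identical(clean_map(bin_map(m))$mask, oracle_median3(m))
  }
})

test_that("overlays paint maps over the vasculature and blend overlaps", {
  vasc <- matrix(seq(0, 1000, length.out = 64), 8, 8)
  empty <- bin_map(matrix(FALSE, 8, 8))
  # no active pixels: pure rescaled grayscale
  rgb <- overlay_maps(list(empty), "red", vasc, opacity = 0.7)
  g <- (vasc - min(vasc)) / diff(range(vasc)) * 255
  for (ch in 1:3) expect_equal(rgb[, , ch], g)
  # full map at opacity 1: uniform color field
  full <- bin_map(matrix(TRUE, 8, 8))
  rgb2 <- overlay_maps(list(full), "#3040FF", vasc, opacity = 1)
  expect_equal(rgb2[, , 1], matrix(0x30, 8, 8))
  expect_equal(rgb2[, , 3], matrix(0xFF, 8, 8))
  # two disjoint maps: union of painted regions, elsewhere grayscale
  m1 <- matrix(FALSE, 8, 8); m1[1:2, ] <- TRUE
  m2 <- matrix(FALSE, 8, 8); m2[7:8, ] <- TRUE
  rgb3 <- overlay_maps(list(bin_map(m1), bin_map(m2)), c("red", "blue"),
                       vasc, opacity = 1)
  painted <- m1 | m2
  expect_equal(rgb3[, , 2][!painted], g[!painted])
  expect_equal(rgb3[, , 1][m1], rep(255, sum(m1)))
  expect_equal(rgb3[, , 3][m2], rep(255, sum(m2)))
  expect_error(overlay_maps(list(empty), "red", matrix(0, 9, 9)), "multiple")
  expect_error(overlay_maps(list(empty, bin_map(matrix(FALSE, 4, 4))),
                            c("red", "blue"), vasc), "shape")
})

test_that("group averaging aligns maps by their reference centers", {
  set.seed(47)
  base <- matrix(0, 21, 21)
  base[8:12, 9:13] <- matrix(runif(25, 0.5, 1), 5, 5)
  m1 <- ev_map(base)
  # same pattern shifted by (5, 0) with the center annotated accordingly
  m2 <- ev_map(iosimap:::shift_matrix(base, 5, 0))
  m2$values[is.na(m2$values)] <- 0
  ga2 <- group_average(list(m1, m2), list(c(10, 10), c(15, 10)))
  ga1 <- group_average(list(m1), list(c(10, 10)))
  expect_equal(ga2$values, ga1$values, tolerance = 1e-12)
  # single map already centered: linear 0-255 rescale of itself
  expect_equal(ga1$values,
               (base - min(base)) / diff(range(base)) * 255,
               tolerance = 1e-12)
  # constant map: degenerate rescale maps to uniform 0
  gac <- group_average(list(ev_map(matrix(4, 9, 9))), list(c(4, 4)))
  expect_equal(gac$values, matrix(0, 9, 9))
  expect_error(group_average(list(), list()), "empty")
})
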