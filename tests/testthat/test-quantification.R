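test_that("map area is pixel count times squared pixel size", {
  m <- matrix(FALSE, 20, 20); m[sample(400, 100)] <- TRUE
  expect_equal(map_area(bin_map(m, px = 5.5)), 100 * 0.0055^2)
  expect_equal(map_area(bin_map(matrix(FALSE, 4, 4))), 0)
})

test_that("a rasterized disc recovers its analytic area within 5%", {
  # 0.226 mm radius disc at 33 um/px (the single-whisker map scale)
  r_px <- 226 / 33
  m <- circle_mask(c(32, 32), c(15.5, 15.5), r_px)
  got <- map_area(bin_map(m, px = 33))
  expect_equal(got, pi * 0.226^2, tolerance = 0.05)
})

test_that("area scales quadratically under upsampling of the same physical map", {
  r_mm <- 0.2
  a <- map_area(bin_map(circle_mask(c(32, 32), c(15.5, 15.5), r_mm * 1000 / 40),
                        px = 40))
  b <- map_area(bin_map(circle_mask(c(64, 64), c(31.5, 31.5), r_mm * 1000 / 20),
                        px = 20))
  expect_equal(a, pi * r_mm^2, tolerance = 0.05)
  expect_equal(b, pi * r_mm^2, tolerance = 0.05)
})

test_that("ellipse fitting matches symmetry and closed-form moments", {
  # filled axis-aligned square: centroid center, equal semi-axes
  sq <- matrix(FALSE, 16, 16); sq[4:11, 6:13] <- TRUE
  f <- fit_ellipse(bin_map(sq, px = 10))
  expect_equal(unname(f$center), c(6.5, 8.5))
  expect_equal(f$semi_major_um, f$semi_minor_um, tolerance = 1e-10)
  # ellipse area matches pixel area (moment-matching constraint)
  expect_equal(pi * f$semi_major_um * f$semi_minor_um,
               sum(sq) * 10^2, tolerance = 1e-10)
  # 2:1 filled rectangle: axis ratio 2, angle 0
  rc <- matrix(FALSE, 24, 40); rc[5:14, 5:24] <- TRUE
  f2 <- fit_ellipse(bin_map(rc, px = 10))
  expect_equal(f2$semi_major_um / f2$semi_minor_um, 2, tolerance = 0.02)
  expect_equal(f2$angle_rad, 0, tolerance = 1e-10)
  # filled disc radius 10 px: semi-axes within 2% of 10 px
  dm <- circle_mask(c(25, 25), c(12, 12), 10)
  f3 <- fit_ellipse(bin_map(dm, px = 1))
  expect_equal(f3$semi_major_um, 10, tolerance = 0.02)
  expect_equal(f3$semi_minor_um, 10, tolerance = 0.02)
  expect_equal(unname(f3$center), c(12, 12))
  expect_error(fit_ellipse(bin_map(matrix(FALSE, 4, 4))), "3 true pixels")
})

test_that("ellipse moments agree with the explicit double-sum oracle", {
  for (seed in 1:8) {
    m <- random_blob(32, seed)
    f <- fit_ellipse(bin_map(m, px = 1), largest_component = FALSE)
    o <- oracle_moments(m)
    expect_equal(unname(f$center), c(o$yb, o$xb), tolerance = 1e-10)
    common <- sqrt((o$uxx - o$uyy)^2 + 4 * o$uxy^2)
    l1 <- (o$uxx + o$uyy + common) / 2
    l2 <- (o$uxx + o$uyy - common) / 2
    sc <- sqrt(o$n / (pi * 2 * sqrt(l1) * 2 * sqrt(l2)))
    expect_equal(f$semi_major_um, 2 * sqrt(l1) * sc, tolerance = 1e-10)
    expect_equal(f$semi_minor_um, 2 * sqrt(l2) * sc, tolerance = 1e-10)
  }
})

test_that("multi-component maps are fitted on the largest component", {
  m <- matrix(FALSE, 20, 20)
  m[2:9, 2:9] <- TRUE          # 64 px
  m[15:17, 15:17] <- TRUE      # 9 px satellite
  f <- fit_ellipse(bin_map(m, px = 1))
  expect_equal(unname(f$center), c(4.5, 4.5))
  expect_identical(f$n_pixels, 64L)
  fall <- fit_ellipse(bin_map(m, px = 1), largest_component = FALSE)
  expect_identical(fall$n_pixels, 73L)
  expect_gt(fall$center[1], f$center[1])
})

test_that("displacements convert centers to micrometres with sign convention", {
  m1 <- circle_mask(c(32, 32), c(10, 10), 4)
  m2 <- circle_mask(c(32, 32), c(10, 30), 4)  # wait: radius 4 at col 30 clips
  f1 <- fit_ellipse(bin_map(m1, px = 5.5))
  expect_equal(displacement(f1, f1), c(dx_um = 0, dy_um = 0))
  # centers (10,10) vs (10,30): map minus reference -> dx = -110 um
  f2 <- list(center = c(row = 10, col = 30), pixel_size_um = 5.5)
  d <- displacement(f1, f2)
  expect_equal(d, c(dx_um = -110, dy_um = 0))
  # antisymmetry
  expect_equal(displacement(f2, f1), -d)
  f3 <- list(center = c(row = 0, col = 0), pixel_size_um = 11)
  expect_error(displacement(f1, f3), "different grids")
})

test_that("two-group MANOVA equals closed-form Hotelling T-squared", {
  set.seed(101)
  for (rep in 1:5) {
    g1 <- matrix(rnorm(12), 6, 2)
    g2 <- matrix(rnorm(12, mean = rep), 6, 2)
    res <- compare_displacements(list(g1, g2))
    expect_equal(res$p_value, oracle_hotelling(g1, g2), tolerance = 1e-10)
    # permuting point order leaves the statistic unchanged
    res2 <- compare_displacements(list(g1[sample(6), ], g2[sample(6), ]))
    expect_equal(res$statistic, res2$statistic, tolerance = 1e-12)
  }
})

test_that("MANOVA detects separated groups and rejects degenerate input", {
  set.seed(103)
  g1 <- matrix(rnorm(12, 0, 0.05), 6, 2)
  g2 <- matrix(rnorm(12, 5, 0.05), 6, 2)
  expect_lt(compare_displacements(list(g1, g2))$p_value, 1e-3)
  # three groups are supported
  g3 <- matrix(rnorm(12, 2, 0.05), 6, 2)
  res3 <- compare_displacements(list(g1, g2, g3))
  expect_lt(res3$p_value, 1e-3)
  expect_error(compare_displacements(list(g1)), "two groups")
  expect_error(compare_displacements(list(g1, g2[1, , drop = FALSE])), ">= 2")
})

test_that("paired area comparison reports means, SEM and both percent changes", {
  pre <- c(0.15, 0.18, 0.14, 0.17, 0.16, 0.16)
  post <- c(0.28, 0.33, 0.25, 0.31, 0.30, 0.32)
  res <- area_change(pre, post)
  expect_equal(res$mean_pre, mean(pre))
  expect_equal(res$sem_post, sd(post) / sqrt(6))
  expect_equal(res$percent_change_of_means,
               100 * (mean(post) - mean(pre)) / mean(pre))
  expect_equal(res$mean_percent_change, 100 * mean((post - pre) / pre))
  ref <- t.test(post, pre, paired = TRUE)
  expect_equal(res$test$p_value, ref$p.value)
  expect_equal(res$test$statistic, unname(ref$statistic))
  # identical lists: t = 0, p = 1
  same <- area_change(pre, pre)
  expect_equal(same$test$statistic, 0)
  expect_equal(same$test$p_value, 1)
  # constant doubling: zero variance of differences is degenerate
  expect_warning(dbl <- area_change(rep(0.2, 6), rep(0.4, 6)), "zero variance")
  expect_equal(dbl$test$p_value, 0)
  expect_error(area_change(pre, post[1:3]), "length")
})

test_that("binary-map input to area_change uses measured areas", {
  maps_pre <- lapply(c(3, 4), function(r)
    bin_map(circle_mask(c(32, 32), c(15, 15), r), px = 33))
  maps_post <- lapply(c(5, 6), function(r)
    bin_map(circle_mask(c(32, 32), c(15, 15), r), px = 33))
  res <- area_change(maps_pre, maps_post)
  expect_equal(res$areas$pre_mm2, vapply(maps_pre, map_area, 0))
  expect_gt(res$mean_post, res$mean_pre)
})

test_that("accumulation curve is 100% everywhere for identical noiseless trials", {
  pcs <- small_phantom(image_size = c(96, 96), blob_sigma_um = 120,
                       n_trials = 3, noise_sd_frac = 0)
  ph <- make_phantom_session(pcs)
  curve <- trial_accumulation_curve(ph$session, threshold_spec(z_cut = -3))
  expect_equal(curve$percent_of_max, rep(100, 3))
  expect_equal(curve$k, 1:3)
  # self-normalization: k = n is exactly 100 even with noise
  pcn <- small_phantom(image_size = c(96, 96), blob_sigma_um = 120,
                       n_trials = 3, noise_sd_frac = 0.004, seed = 5,
                       amplitude = -5e-3)
  cn <- trial_accumulation_curve(pcn, threshold_spec(z_cut = -3))
  expect_identical(cn$percent_of_max[3], 100)
})

test_that("accumulation errors when the full-trial map is empty", {
  pcs <- small_phantom(image_size = c(96, 96), amplitude = 0,
                       noise_sd_frac = 0, n_trials = 2)
  # amplitude 0, no noise: constant movie -> zero map -> zero variance
  expect_error(trial_accumulation_curve(pcs, threshold_spec(z_cut = -3)),
               "variance|zero area")
})
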