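cal1 <- spatial_calibration(22, 1, 1, 1)   # no downsampling
cal4 <- spatial_calibration(33, 4, 1, 4)

test_that("Gaussian kernel follows the 2*ceil(2*sigma)+1 size rule", {
  expect_identical(gaussian_spec(0.5)$kernel_size, 3L)
  expect_identical(gaussian_spec(1)$kernel_size, 5L)
  expect_identical(gaussian_spec(1.3)$kernel_size, 7L)
  expect_equal(sum(gaussian_spec(0.5)$weights), 1)
  expect_error(gaussian_spec(0), "sigma")
})

test_that("Gaussian filtering preserves constants and matches the explicit kernel", {
  tr <- trial_stack(array(3.7, c(8, 8, 2)), 1, cal1)
  out <- gaussian_filter_frames(tr)
  expect_equal(out$frames, array(3.7, c(8, 8, 2)), tolerance = 1e-14)
  # single bright pixel reproduces the hand-computed 3x3 sigma=0.5 kernel
  w <- exp(-(-1:1)^2 / (2 * 0.25)); w <- w / sum(w)
  fr <- array(0, c(9, 9, 1)); fr[5, 5, 1] <- 1
  img <- gaussian_filter_frames(trial_stack(fr, 0, cal1))$frames[, , 1]
  expect_equal(img[4:6, 4:6], outer(w, w), tolerance = 1e-14)
  expect_equal(sum(img), 1, tolerance = 1e-14)
})

test_that("filtering matches a brute-force replicated-border convolution", {
  set.seed(21)
  for (sg in c(0.5, 1)) {
    m <- matrix(runif(12 * 10), 12, 10)
    spec <- gaussian_spec(sg)
    got <- gaussian_filter_image(m, spec)
    expect_equal(got, oracle_gauss_filter(m, spec$weights), tolerance = 1e-12)
  }
})

test_that("block downsampling averages non-overlapping blocks and drops partial ones", {
  expect_equal(downsample(matrix(5, 8, 8), 4), matrix(5, 2, 2))
  expect_equal(downsample(matrix(1:16, 4, 4, byrow = TRUE), 4),
               matrix(8.5, 1, 1))
  m <- matrix(runif(81), 9, 9)
  expect_identical(downsample(m, 1), m)
  expect_equal(downsample(m, 4), oracle_block_mean(m, 4))  # 9 -> 2, crop
  expect_equal(dim(downsample(m, 4)), c(2L, 2L))
  expect_error(downsample(m, 10), "exceeds")
  # decimation option picks the top-left pixel of each block
  expect_equal(downsample(m, 4, method = "decimate"),
               m[c(1, 5), c(1, 5)])
})

test_that("baseline averages the 0.9 s of frames strictly before onset", {
  acq <- acquisition_config()
  tr <- index_trial()
  # frame value = 0-based index; baseline frames are indices 1..9
  expect_equal(baseline_image(tr, acq), matrix(5, 8, 8))
  trc <- trial_stack(array(2.5, c(8, 8, 40)), 10, cal1)
  expect_equal(baseline_image(trc, acq), matrix(2.5, 8, 8))
})

test_that("post-stimulus bins cover 0.5-2.0 s in five 3-frame means", {
  acq <- acquisition_config()
  bins <- poststim_bins(index_trial(), acq)
  expect_length(bins, 5)
  expect_equal(vapply(bins, function(b) b[1, 1], 0), c(16, 19, 22, 25, 28))
  binsc <- poststim_bins(trial_stack(array(7, c(8, 8, 40)), 10, cal1), acq)
  for (b in binsc) expect_equal(b, matrix(7, 8, 8))
})

test_that("baseline and bin means agree with a brute-force frame-indexing oracle", {
  # random valid configs: every window an integral number of frames
  set.seed(33)
  for (rep in 1:10) {
    rate <- sample(c(5, 10, 20), 1)
    nb <- sample(3:8, 1)
    off <- sample(1:4, 1)
    bw <- sample(1:3, 1)
    nbin <- sample(2:5, 1)
    acq <- acquisition_config(frame_rate_hz = rate,
                              pre_stim_s = (nb + 1) / rate,
                              post_stim_s = (off + bw * nbin + 1) / rate,
                              baseline_window_s = nb / rate,
                              bin_width_s = bw / rate,
                              post_start_offset_s = off / rate,
                              post_total_s = bw * nbin / rate)
    onset <- nb + 1
    nfr <- onset + off + bw * nbin + 1
    fr <- array(runif(6 * 6 * nfr), c(6, 6, nfr))
    tr <- trial_stack(fr, onset, cal1)
    # oracle: direct frame indexing (R 1-based)
    base_o <- apply(fr[, , (onset - nb + 1):onset, drop = FALSE], c(1, 2), mean)
    expect_equal(baseline_image(tr, acq), base_o, tolerance = 1e-12)
    bins <- poststim_bins(tr, acq)
    for (k in seq_len(nbin)) {
      i0 <- onset + off + (k - 1) * bw + 1
      bin_o <- apply(fr[, , i0:(i0 + bw - 1), drop = FALSE], c(1, 2), mean)
      expect_equal(bins[[k]], bin_o, tolerance = 1e-12)
    }
  }
})

test_that("delta-R/R is zero for constant movies and exact for known ratios", {
  acq <- acquisition_config()
  d <- drr_trial(trial_stack(array(100, c(8, 8, 40)), 10, cal1), acq)
  expect_equal(d$bins, array(0, c(8, 8, 5)))
  expect_identical(d$n_bins, 5L)
  # baseline 100 everywhere, post-stimulus frames at 99 -> -0.01
  fr <- array(100, c(8, 8, 40))
  fr[, , 16:30] <- 99
  d2 <- drr_trial(trial_stack(fr, 10, cal1), acq)
  expect_equal(d2$bins, array(-0.01, c(8, 8, 5)), tolerance = 1e-12)
})

test_that("a zero baseline pixel is reported with its location", {
  acq <- acquisition_config()
  fr <- array(100, c(8, 8, 40))
  fr[2:4, 4:6, ] <- 0     # 3x3 zero block survives the Gaussian filter
  expect_error(drr_trial(trial_stack(fr, 10, cal1), acq),
               "row 2, col 4")
})

test_that("delta-R/R is invariant to global gain", {
  acq <- acquisition_config()
  set.seed(17)
  fr <- array(runif(8 * 8 * 40, 50, 150), c(8, 8, 40))
  d1 <- drr_trial(trial_stack(fr, 10, cal1), acq)
  d2 <- drr_trial(trial_stack(fr * 3.7, 10, cal1), acq)
  expect_equal(d1$bins, d2$bins, tolerance = 1e-12)
})

test_that("pipeline order is filter -> downsample -> bins -> ratio", {
  acq <- acquisition_config()
  set.seed(29)
  fr <- array(runif(16 * 16 * 40, 50, 150), c(16, 16, 40))
  tr <- trial_stack(fr, 10, cal4)
  d <- drr_trial(tr, acq)
  # manual reference: sequential ops in the documented order
  filt <- gaussian_filter_frames(tr)
  down <- downsample(filt)
  B <- baseline_image(down, acq)
  bins <- poststim_bins(down, acq)
  man <- vapply(bins, function(P) (P - B) / B, matrix(0, 4, 4))
  expect_equal(d$bins, man, tolerance = 1e-12)
  expect_equal(d$pixel_size_um, 33)
})

test_that("evoked map averages trials then sums bins (linearity)", {
  acq <- acquisition_config(n_trials = 3)
  set.seed(41)
  trials <- lapply(1:3, function(i)
    trial_stack(array(runif(8 * 8 * 40, 50, 150), c(8, 8, 40)), 10, cal1))
  s <- session(trials, config = acq)
  ev <- evoked_map(s)
  drrs <- lapply(trials, drr_trial, config = acq)
  # mean-then-sum equals sum-then-mean
  ref1 <- Reduce(`+`, lapply(drrs, function(d) rowSums(d$bins, dims = 2))) / 3
  expect_equal(ev$values, ref1, tolerance = 1e-12)
  expect_identical(ev$n_trials_used, 3L)
  # identical trials: average equals the single-trial map
  s2 <- session(rep(trials[1], 3), config = acq)
  expect_equal(evoked_map(s2)$values, rowSums(drrs[[1]]$bins, dims = 2),
               tolerance = 1e-12)
  expect_error(evoked_map(s, trials = integer(0)), "empty")
})

test_that("trials with opposite responses cancel in the evoked map", {
  d <- structure(list(bins = array(0.01, c(4, 4, 5)), n_bins = 5L,
                      pixel_size_um = 22), class = "iosi_drr")
  d2 <- d; d2$bins <- -d$bins
  ev <- evoked_map(list(d, d2))
  expect_equal(ev$values, matrix(0, 4, 4))
})

test_that("a temporally constant movie maps to an exactly zero evoked map", {
  # arbitrary spatial content, constant in time
  set.seed(55)
  img <- matrix(runif(256, 100, 5000), 16, 16)
  fr <- array(rep(img, 40), c(16, 16, 40))
  s <- session(list(trial_stack(fr, 10, cal4)), config = acquisition_config())
  ev <- evoked_map(s)
  expect_identical(max(abs(ev$values)), 0)
})

test_that("fused filter+downsample equals the sequential operations", {
  set.seed(61)
  fr <- array(runif(16 * 16 * 4), c(16, 16, 4))
  spec <- gaussian_spec(0.5)
  fused <- iosimap:::filter_and_downsample(fr, spec, 4L)
  seqntl <- downsample(gaussian_filter_frames(
    trial_stack(fr, 0, cal4), spec)$frames, 4L)
  expect_equal(fused, seqntl, tolerance = 1e-12)
})
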