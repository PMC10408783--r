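# Synthetic phantom: trial-structured reflectance movies with known ground
# truth, emulating widefield IOSI acquisition. Per trial,
#   R(x, t) = V(x) * (1 + amplitude * G(x) * s(t)) * (1 + eps),
# with V the vascular baseline image, G a spatial Gaussian response profile
# normalized to peak 1, s(t) a gamma-shaped hemodynamic time course in
# [0, 1], and eps iid N(0, noise_sd_frac) per pixel and frame
# (multiplicative noise approximating shot noise at >= 1e4 photoelectrons).

#' Hemodynamic response time-course specification
#'
#' Gamma-shaped response: zero until `onset_delay_s` after stimulus onset,
#' rising to 1 at `onset_delay_s + time_to_peak_s`, then decaying; the
#' gamma shape parameter is solved numerically so the curve's full width
#' at half maximum equals `fwhm_s`.
#'
#' Defaults (0.3 s delay, 1.2 s to peak, 3 s FWHM) describe a sustained
#' response that peaks about 1.5 s after stimulus onset and stays elevated
#' through the 0.5–2 s analysis window, as measured intrinsic signals do
#' during a 1.5 s stimulus.
#'
#' @param onset_delay_s response onset delay after stimulus onset, seconds.
#' @param time_to_peak_s rise time from response onset to peak, seconds.
#' @param fwhm_s full width at half maximum of the response, seconds.
#' @return Object of class `iosi_hrf` (includes the solved gamma `shape`).
#' @export
hrf_spec <- function(onset_delay_s = 0.3, time_to_peak_s = 1.2,
                     fwhm_s = 3.0) {
  stopifnot(onset_delay_s >= 0, time_to_peak_s > 0, fwhm_s > 0)
  fwhm_of <- function(alpha) {
    g <- function(x) alpha * (log(x) + 1 - x) - log(0.5)
    x1 <- uniroot(g, c(1e-12, 1), tol = 1e-12)$root
    x2 <- uniroot(g, c(1, 1e6), tol = 1e-12)$root
    time_to_peak_s * (x2 - x1)
  }
  shape <- uniroot(function(la) fwhm_of(exp(la)) - fwhm_s,
                   c(log(0.05), log(500)), tol = 1e-10)$root
  structure(list(onset_delay_s = onset_delay_s,
                 time_to_peak_s = time_to_peak_s,
                 fwhm_s = fwhm_s, shape = exp(shape)),
            class = "iosi_hrf")
}

#' Evaluate the response time course
#'
#' @param hrf an [hrf_spec()].
#' @param t time since stimulus onset, seconds (vectorized).
#' @return Response fraction in `[0, 1]`.
#' @export
hrf_value <- function(hrf, t) {
  tau <- t - hrf$onset_delay_s
  x <- pmax(tau, 0) / hrf$time_to_peak_s
  a <- hrf$shape
  s <- ifelse(tau <= 0, 0, x^a * exp(a * (1 - x)))
  pmin(pmax(s, 0), 1)
}

#' Per-frame response samples for a trial
#'
#' Samples [hrf_value()] at each frame time `(i - onset_frame) /
#' frame_rate_hz` of a trial, i the 0-based frame index; frames before the
#' response onset are exactly 0.
#'
#' @param hrf an [hrf_spec()].
#' @param config an [acquisition_config()].
#' @return Numeric vector, one value in `[0, 1]` per frame.
#' @export
response_timecourse <- function(hrf, config = acquisition_config()) {
  nfr <- trial_frame_count(config)
  onset <- frames_per_window(config, config$pre_stim_s, "pre_stim_s")
  peak_t <- hrf$onset_delay_s + hrf$time_to_peak_s
  if (peak_t > config$post_stim_s)
    stop("response_timecourse: response peak (", peak_t,
         " s) falls outside the ", config$post_stim_s, " s trial")
  t <- ((0:(nfr - 1)) - onset) / config$frame_rate_hz
  hrf_value(hrf, t)
}

#' Phantom configuration
#'
#' Defines a synthetic IOSI session. The defaults emulate the standard
#' protocol at a computationally tractable grid: a 512 x 512 raw grid of
#' 8.25 um on-sample pixels (4.22 mm field of view; 33 um analysis pixels
#' after the x4 downsample), a 4 mm-diameter circular cranial window, one
#' activation blob of Gaussian width 192 um (half-peak area 0.160 mm^2,
#' the scale of a single-whisker map), peak fractional reflectance change
#' -1e-3, and per-pixel per-frame multiplicative noise of 0.7% (shot noise
#' at a 20,000 e- full well).
#'
#' @param image_size raw grid `c(rows, cols)`.
#' @param calibration a [spatial_calibration()] for the raw grid.
#' @param blob_center blob center `(row, col)` in 0-based raw pixels
#'   (fractional allowed); default = image center.
#' @param blob_sigma_um Gaussian sigma of the response profile in
#'   micrometres; `Inf` gives a spatially uniform response.
#' @param amplitude peak fractional reflectance change (negative;
#'   plausible range -1e-2 ... -1e-5).
#' @param hrf an [hrf_spec()].
#' @param noise_sd_frac per-pixel per-frame multiplicative noise SD.
#' @param noise_model `"gaussian"` (default) or `"poisson"` (photon
#'   counts with mean `baseline_level`, ignoring `noise_sd_frac`).
#' @param baseline_level mean baseline reflectance, counts.
#' @param vessel_contrast fractional intensity reduction of vessel pixels.
#' @param n_vessels number of simulated surface vessels.
#' @param window_radius_mm radius of the circular cranial-window mask.
#' @param n_trials trials per synthetic session.
#' @param seed RNG seed; fixed seed gives bit-reproducible output.
#' @return Object of class `iosi_phantom_config`.
#' @export
phantom_config <- function(image_size = c(512L, 512L),
                           calibration = spatial_calibration(33, 4, 1, 4),
                           blob_center = NULL,
                           blob_sigma_um = 192,
                           amplitude = -1e-3,
                           hrf = hrf_spec(),
                           noise_sd_frac = 0.007,
                           noise_model = c("gaussian", "poisson"),
                           baseline_level = 10000,
                           vessel_contrast = 0.35,
                           n_vessels = 12L,
                           window_radius_mm = 2.0,
                           n_trials = 30L,
                           seed = 1L) {
  noise_model <- match.arg(noise_model)
  image_size <- as.integer(image_size)
  if (is.null(blob_center)) blob_center <- (image_size - 1) / 2
  if (any(blob_center < 0) || any(blob_center > image_size - 1))
    stop("phantom_config: blob_center lies outside the image")
  if (amplitude > 0)
    stop("phantom_config: amplitude must be <= 0 (reflectance decrease)")
  if (abs(amplitude) > 1e-1)
    stop("phantom_config: |amplitude| ", abs(amplitude),
         " is far outside the intrinsic-signal range")
  if (noise_sd_frac < 0) stop("phantom_config: noise_sd_frac must be >= 0")
  stopifnot(baseline_level > 0, vessel_contrast >= 0, vessel_contrast < 1,
            n_trials >= 1)
  structure(list(image_size = image_size, calibration = calibration,
                 blob_center = blob_center, blob_sigma_um = blob_sigma_um,
                 amplitude = amplitude, hrf = hrf,
                 noise_sd_frac = noise_sd_frac, noise_model = noise_model,
                 baseline_level = baseline_level,
                 vessel_contrast = vessel_contrast,
                 n_vessels = as.integer(n_vessels),
                 window_radius_mm = window_radius_mm,
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "iosi_phantom_config")
}

# independent per-purpose sub-seeds derived from the master seed, so each
# trial (and the vasculature) is reproducible regardless of call order
phantom_seeds <- function(pcfg) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(pcfg$seed)
  list(vasculature = sample.int(.Machine$integer.max - 1L, 1L),
       trials = sample.int(.Machine$integer.max - 1L, pcfg$n_trials))
}

#' Synthetic vasculature image
#'
#' Baseline-level field with seeded dark curvilinear vessels (smoothed
#' random walks of width 2–6 raw pixels at `vessel_contrast` intensity
#' reduction). Deterministic for a fixed seed.
#'
#' @param pcfg a [phantom_config()].
#' @return Numeric matrix (raw grid) of reflectance counts.
#' @export
make_vasculature <- function(pcfg) {
  sd_ <- phantom_seeds(pcfg)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(sd_$vasculature)
  n <- pcfg$image_size[1]; m <- pcfg$image_size[2]
  vessel <- matrix(FALSE, n, m)
  for (v in seq_len(pcfg$n_vessels)) {
    side <- sample.int(4L, 1L)
    pos <- switch(side,
                  c(1, runif(1, 1, m)),            # top
                  c(n, runif(1, 1, m)),            # bottom
                  c(runif(1, 1, n), 1),            # left
                  c(runif(1, 1, n), m))            # right
    ang <- switch(side, pi / 2, -pi / 2, 0, pi) + runif(1, -0.5, 0.5)
    width <- sample(2:6, 1L)
    half <- width / 2
    hw <- ceiling(half)
    nsteps <- round(1.5 * max(n, m))
    for (step in seq_len(nsteps)) {
      ang <- ang + rnorm(1, 0, 0.06)
      pos <- pos + c(sin(ang), cos(ang))
      r0 <- round(pos[1]); c0 <- round(pos[2])
      if (r0 < 1 - hw || r0 > n + hw || c0 < 1 - hw || c0 > m + hw) break
      rr <- max(1, r0 - hw):min(n, r0 + hw)
      cc <- max(1, c0 - hw):min(m, c0 + hw)
      patch <- outer(rr - pos[1], cc - pos[2],
                     function(a, b) a^2 + b^2 <= half^2)
      vessel[rr, cc] <- vessel[rr, cc] | patch
    }
  }
  V <- matrix(pcfg$baseline_level, n, m)
  V[vessel] <- pcfg$baseline_level * (1 - pcfg$vessel_contrast)
  V
}

# spatial response profile on the raw grid, peak exactly 1
phantom_blob <- function(pcfg) {
  n <- pcfg$image_size[1]; m <- pcfg$image_size[2]
  if (!is.finite(pcfg$blob_sigma_um)) return(matrix(1, n, m))
  sig_px <- pcfg$blob_sigma_um / raw_pixel_size_um(pcfg$calibration)
  r <- matrix(0:(n - 1), n, m)
  c_ <- matrix(0:(m - 1), n, m, byrow = TRUE)
  exp(-((r - pcfg$blob_center[1])^2 + (c_ - pcfg$blob_center[2])^2) /
        (2 * sig_px^2))
}

#' Cranial-window mask of a phantom, in analysis pixels
#' @param pcfg a [phantom_config()].
#' @return `list(center_row, center_col, radius_px)` (0-based center).
#' @export
phantom_window <- function(pcfg) {
  f <- pcfg$calibration$downsample_factor
  na <- pcfg$image_size %/% f
  apx <- analysis_pixel_size_um(pcfg$calibration)
  list(center_row = (na[1] - 1) / 2, center_col = (na[2] - 1) / 2,
       radius_px = pcfg$window_radius_mm * 1000 / apx)
}

#' Ground truth of a phantom
#'
#' Closed-form truth derived from the configuration: the blob center on
#' the analysis grid, the area enclosed by the half-peak contour of the
#' spatial profile (`pi * (sigma * sqrt(2 ln 2))^2`), the implanted peak
#' amplitude, and the per-frame response time course.
#'
#' @param pcfg a [phantom_config()].
#' @param config an [acquisition_config()].
#' @return List: `true_center` (0-based analysis-grid `(row, col)`),
#'   `true_area_mm2`, `true_amplitude`, `timecourse`.
#' @export
phantom_ground_truth <- function(pcfg, config = acquisition_config()) {
  f <- pcfg$calibration$downsample_factor
  center_a <- (pcfg$blob_center + 0.5) / f - 0.5
  area <- if (is.finite(pcfg$blob_sigma_um)) {
    pi * (pcfg$blob_sigma_um * sqrt(2 * log(2)) * 1e-3)^2
  } else NA_real_
  list(true_center = c(row = center_a[1], col = center_a[2]),
       true_area_mm2 = area,
       true_amplitude = pcfg$amplitude,
       timecourse = response_timecourse(pcfg$hrf, config))
}

#' Synthesize one phantom trial
#'
#' Bit-reproducible for a fixed `(seed, i)`: every trial has its own
#' RNG sub-stream derived from the master seed.
#'
#' @param pcfg a [phantom_config()].
#' @param config an [acquisition_config()].
#' @param i trial index (1-based).
#' @param vasculature optional precomputed [make_vasculature()] image.
#' @return An [trial_stack()].
#' @export
phantom_trial <- function(pcfg, config = acquisition_config(), i = 1L,
                          vasculature = NULL) {
  if (i < 1L || i > pcfg$n_trials)
    stop("phantom_trial: trial index out of range")
  V <- if (is.null(vasculature)) make_vasculature(pcfg) else vasculature
  G <- phantom_blob(pcfg)
  s <- response_timecourse(pcfg$hrf, config)
  onset <- frames_per_window(config, config$pre_stim_s, "pre_stim_s")
  sd_ <- phantom_seeds(pcfg)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(sd_$trials[i])
  if (pcfg$noise_model == "poisson") {
    nfr <- length(s)
    fr <- array(0, c(dim(V), nfr))
    for (t in seq_len(nfr)) {
      lam <- V * (1 + pcfg$amplitude * G * s[t])
      fr[, , t] <- rpois(length(lam), lam)
    }
  } else {
    fr <- cpp_phantom_stack(V, G, s, pcfg$amplitude, pcfg$noise_sd_frac)
  }
  trial_stack(fr, onset, pcfg$calibration)
}

#' Synthesize a complete phantom session with ground truth
#'
#' @param pcfg a [phantom_config()].
#' @param config an [acquisition_config()]; its `n_trials` is overridden
#'   by the phantom's.
#' @return List with `session` (an [session()], window mask included) and
#'   `truth` ([phantom_ground_truth()]).
#' @export
make_phantom_session <- function(pcfg, config = acquisition_config()) {
  config$n_trials <- pcfg$n_trials
  V <- make_vasculature(pcfg)
  trials <- lapply(seq_len(pcfg$n_trials), function(i)
    phantom_trial(pcfg, config, i, vasculature = V))
  list(session = session(trials, V, config, phantom_window(pcfg)),
       truth = phantom_ground_truth(pcfg, config))
}

#' Per-trial delta-R/R of a phantom, synthesized trial-by-trial
#'
#' Equivalent to `lapply(make_phantom_session(...)$session$trials,
#' drr_trial, ...)` but never holds more than one raw trial in memory, so
#' full-size sessions can be processed cheaply.
#'
#' @param pcfg a [phantom_config()].
#' @param config an [acquisition_config()].
#' @param ... passed to [drr_trial()].
#' @return List of `iosi_drr` objects.
#' @export
phantom_drr_trials <- function(pcfg, config = acquisition_config(),
                               spec = gaussian_spec(), ds_method = "mean") {
  V <- make_vasculature(pcfg)
  f <- pcfg$calibration$downsample_factor
  fast <- ds_method == "mean" && pcfg$noise_model == "gaussian" &&
    all(pcfg$image_size %% f == 0)
  if (!fast) {
    return(lapply(seq_len(pcfg$n_trials), function(i) {
      tr <- phantom_trial(pcfg, config, i, vasculature = V)
      drr_trial(tr, config, spec = spec, ds_method = ds_method)
    }))
  }
  G <- phantom_blob(pcfg)
  s <- response_timecourse(pcfg$hrf, config)
  onset <- frames_per_window(config, config$pre_stim_s, "pre_stim_s")
  apx <- analysis_pixel_size_um(pcfg$calibration)
  sd_ <- phantom_seeds(pcfg)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  lapply(seq_len(pcfg$n_trials), function(i) {
    set.seed(sd_$trials[i])
    proc <- cpp_phantom_processed(V, G, s, pcfg$amplitude,
                                  pcfg$noise_sd_frac, spec$weights, f)
    ptrial <- structure(list(frames = proc, onset_frame = onset,
                             calibration = pcfg$calibration),
                        class = "iosi_trial")
    drr_from_processed(ptrial, config, apx)
  })
}

#' Stimulus waveform samples (metadata utility)
#'
#' Sine waveform of a vibrotactile stimulus (e.g. 10 or 100 Hz for
#' 1.5 s), sampled for export to CSV; a bookkeeping aid, not a hardware
#' driver.
#'
#' @param freq_hz sine frequency.
#' @param duration_s stimulus duration.
#' @param sample_rate_hz output sampling rate.
#' @param amplitude peak amplitude (arbitrary units).
#' @return Data frame with `time_s`, `value`.
#' @export
stim_waveform <- function(freq_hz = 10, duration_s = 1.5,
                          sample_rate_hz = 1000, amplitude = 1) {
  t <- seq(0, duration_s, by = 1 / sample_rate_hz)
  data.frame(time_s = t, value = amplitude * sin(2 * pi * freq_hz * t))
}
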