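#' Acquisition configuration
#'
#' Describes the timing structure of a triggered IOSI trial: frame rate,
#' pre/post-stimulus durations, and the averaging windows used by the
#' \eqn{\Delta R/R} pipeline. The defaults reproduce the standard protocol:
#' 10 Hz acquisition starting 1 s before stimulus onset and running 3 s
#' after it (40 frames/trial), a 0.9 s (nine-frame) baseline window, and
#' five 0.3 s post-stimulus bins covering 0.5–2.0 s after onset.
#'
#' Every window must convert to a whole number of frames at the configured
#' frame rate; a non-integral window is a hard error rather than a silent
#' rounding, because the published frame counts (9 baseline frames, 3-frame
#' bins) define the analysis.
#'
#' @param frame_rate_hz frames per second (> 0).
#' @param pre_stim_s seconds of recording before stimulus onset.
#' @param post_stim_s seconds of recording after stimulus onset.
#' @param stim_duration_s stimulus duration in seconds (metadata only).
#' @param n_trials trials per session.
#' @param baseline_window_s seconds immediately before onset averaged into
#'   the baseline reflectance image; must not exceed `pre_stim_s`.
#' @param bin_width_s seconds per post-stimulus bin.
#' @param post_start_offset_s seconds after onset at which binning starts.
#' @param post_total_s total seconds of binned post-stimulus data;
#'   `post_start_offset_s + post_total_s` must not exceed `post_stim_s`.
#' @return An object of class `iosi_acq`.
#' @examples
#' acq <- acquisition_config()
#' frames_per_window(acq, acq$baseline_window_s)  # 9
#' @export
acquisition_config <- function(frame_rate_hz = 10,
                               pre_stim_s = 1.0,
                               post_stim_s = 3.0,
                               stim_duration_s = 1.5,
                               n_trials = 30,
                               baseline_window_s = 0.9,
                               bin_width_s = 0.3,
                               post_start_offset_s = 0.5,
                               post_total_s = 1.5) {
  cfg <- structure(list(
    frame_rate_hz = frame_rate_hz,
    pre_stim_s = pre_stim_s,
    post_stim_s = post_stim_s,
    stim_duration_s = stim_duration_s,
    n_trials = as.integer(n_trials),
    baseline_window_s = baseline_window_s,
    bin_width_s = bin_width_s,
    post_start_offset_s = post_start_offset_s,
    post_total_s = post_total_s
  ), class = "iosi_acq")
  validate_acquisition_config(cfg)
  cfg
}

validate_acquisition_config <- function(cfg) {
  stopifnot(is.numeric(cfg$frame_rate_hz), cfg$frame_rate_hz > 0)
  num <- c("pre_stim_s", "post_stim_s", "stim_duration_s",
           "baseline_window_s", "bin_width_s", "post_start_offset_s",
           "post_total_s")
  for (f in num) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("acquisition_config: field '", f, "' must be a non-negative number")
  }
  if (cfg$n_trials < 1L)
    stop("acquisition_config: n_trials must be >= 1")
  if (cfg$baseline_window_s > cfg$pre_stim_s + 1e-12)
    stop("acquisition_config: baseline_window_s (", cfg$baseline_window_s,
         " s) exceeds pre_stim_s (", cfg$pre_stim_s, " s)")
  if (cfg$post_start_offset_s + cfg$post_total_s > cfg$post_stim_s + 1e-12)
    stop("acquisition_config: post_start_offset_s + post_total_s exceeds ",
         "post_stim_s")
  if (cfg$post_total_s > 0 && cfg$bin_width_s <= 0)
    stop("acquisition_config: bin_width_s must be > 0")
  # every window must be a whole number of frames (checked here so an
  # invalid config fails at construction, not mid-pipeline)
  for (f in c("pre_stim_s", "post_stim_s", "baseline_window_s",
              "bin_width_s", "post_start_offset_s", "post_total_s")) {
    frames_per_window(cfg, cfg[[f]], window_name = f)
  }
  nb <- cfg$post_total_s / cfg$bin_width_s
  if (abs(nb - round(nb)) > 1e-6)
    stop("acquisition_config: post_total_s is not a whole number of bins")
  invisible(cfg)
}

#' Frames contained in a time window
#'
#' Converts a window duration to an exact frame count at the configured
#' frame rate. Errors if the product is not integral (within 1e-6), naming
#' the offending window: the averaging windows define the analysis, so
#' silent rounding is never performed.
#'
#' @param config an [acquisition_config()].
#' @param window_s window duration in seconds.
#' @param window_name label used in the error message.
#' @return Integer frame count.
#' @examples
#' frames_per_window(acquisition_config(), 0.9)  # 9
#' frames_per_window(acquisition_config(), 0.3)  # 3
#' @export
frames_per_window <- function(config, window_s, window_name = "window") {
  x <- window_s * config$frame_rate_hz
  if (abs(x - round(x)) > 1e-6)
    stop("window '", window_name, "' (", window_s, " s) is not a whole ",
         "number of frames at ", config$frame_rate_hz, " Hz (", x, " frames)")
  as.integer(round(x))
}

#' Total frames in one trial
#' @param config an [acquisition_config()].
#' @return Integer: `(pre_stim_s + post_stim_s) * frame_rate_hz`.
#' @export
trial_frame_count <- function(config) {
  frames_per_window(config, config$pre_stim_s, "pre_stim_s") +
    frames_per_window(config, config$post_stim_s, "post_stim_s")
}

#' Number of post-stimulus bins
#' @param config an [acquisition_config()].
#' @return Integer bin count (`post_total_s / bin_width_s`).
#' @export
n_poststim_bins <- function(config) {
  as.integer(round(config$post_total_s / config$bin_width_s))
}

#' @export
print.iosi_acq <- function(x, ...) {
  cat("IOSI acquisition config\n")
  cat(sprintf("  %g Hz, %g s pre / %g s post (%d frames/trial), %d trials\n",
              x$frame_rate_hz, x$pre_stim_s, x$post_stim_s,
              trial_frame_count(x), x$n_trials))
  cat(sprintf("  baseline %g s (%d frames); %d bins of %g s from %g s post-onset\n",
              x$baseline_window_s,
              frames_per_window(x, x$baseline_window_s),
              n_poststim_bins(x), x$bin_width_s, x$post_start_offset_s))
  invisible(x)
}
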