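#' Trial reflectance stack
#'
#' One trial's reflectance movie plus timing and spatial metadata. Frames
#' are stored as a numeric array of dimension `rows x cols x time` (the R
#' image convention); `onset_frame` is the 0-based index of the first frame
#' acquired at or after stimulus onset, so with the default 10 Hz / 1 s
#' pre-stimulus protocol `onset_frame = 10` and the nine baseline frames
#' are the 0-based indices 1–9.
#'
#' @param frames numeric array `rows x cols x n_frames`, non-negative
#'   reflectance counts.
#' @param onset_frame 0-based index of the first at/after-onset frame.
#' @param calibration a [spatial_calibration()].
#' @return An object of class `iosi_trial`.
#' @export
trial_stack <- function(frames, onset_frame, calibration) {
  if (length(dim(frames)) != 3L)
    stop("trial_stack: frames must be a rows x cols x time array")
  if (!all(is.finite(frames)))
    stop("trial_stack: frames contain non-finite values")
  if (min(frames) < 0)
    stop("trial_stack: reflectance counts must be >= 0")
  onset_frame <- as.integer(onset_frame)
  if (onset_frame < 0 || onset_frame >= dim(frames)[3])
    stop("trial_stack: onset_frame ", onset_frame,
         " outside the ", dim(frames)[3], "-frame stack")
  if (!inherits(calibration, "iosi_calibration"))
    stop("trial_stack: calibration must be a spatial_calibration()")
  structure(list(frames = frames,
                 onset_frame = onset_frame,
                 calibration = calibration),
            class = "iosi_trial")
}

#' @export
print.iosi_trial <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("IOSI trial stack: %d x %d px, %d frames, onset at frame %d (0-based)\n",
              d[1], d[2], d[3], x$onset_frame))
  print(x$calibration)
  invisible(x)
}

# check a trial against an acquisition config; used by the delta-R/R ops
check_trial_timing <- function(trial, config) {
  nb <- frames_per_window(config, config$baseline_window_s,
                          "baseline_window_s")
  off <- frames_per_window(config, config$post_start_offset_s,
                           "post_start_offset_s")
  bw <- frames_per_window(config, config$bin_width_s, "bin_width_s")
  nbins <- n_poststim_bins(config)
  nfr <- dim(trial$frames)[3]
  if (trial$onset_frame < nb)
    stop("trial has ", trial$onset_frame, " pre-onset frames; baseline ",
         "window needs ", nb)
  if (nfr < trial$onset_frame + off + nbins * bw)
    stop("trial has ", nfr, " frames; post-stimulus binning needs ",
         trial$onset_frame + off + nbins * bw)
  list(n_baseline = nb, offset = off, bin_width = bw, n_bins = nbins)
}
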