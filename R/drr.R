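# The delta-R/R core: baseline and post-stimulus bin averaging, per-trial
# fractional reflectance change, and the trial-averaged bin-summed evoked
# map. The processing order is fixed: Gaussian filter -> spatial downsample
# -> temporal averaging -> delta-R/R. The order changes numerical results
# (filtering and the ratio do not commute), so it is frozen and documented.

#' Baseline reflectance image of one trial
#'
#' Pixelwise mean of the `baseline_window_s` frames strictly before
#' `onset_frame` (with the defaults: the nine frames at 0-based indices
#' `onset_frame - 9 ... onset_frame - 1`).
#'
#' @param trial an [trial_stack()].
#' @param config an [acquisition_config()].
#' @return Numeric matrix (same grid as the trial's frames).
#' @export
baseline_image <- function(trial, config = acquisition_config()) {
  tm <- check_trial_timing(trial, config)
  idx <- (trial$onset_frame - tm$n_baseline + 1):trial$onset_frame  # 1-based
  rowMeans(trial$frames[, , idx, drop = FALSE], dims = 2)
}

#' Post-stimulus bin images of one trial
#'
#' Consecutive non-overlapping bin means of width `bin_width_s`, starting
#' `post_start_offset_s` after onset and covering `post_total_s` in total
#' (defaults: five 3-frame bins over 0.5–2.0 s post-onset).
#'
#' @inheritParams baseline_image
#' @return List of numeric matrices, one per bin.
#' @export
poststim_bins <- function(trial, config = acquisition_config()) {
  tm <- check_trial_timing(trial, config)
  start0 <- trial$onset_frame + tm$offset        # 0-based first binned frame
  lapply(seq_len(tm$n_bins), function(k) {
    idx <- (start0 + (k - 1) * tm$bin_width + 1):(start0 + k * tm$bin_width)
    rowMeans(trial$frames[, , idx, drop = FALSE], dims = 2)
  })
}

#' Per-trial delta-R/R bins
#'
#' Runs the full per-trial pipeline: Gaussian filter, spatial block
#' downsample, baseline and bin averaging, then
#' \eqn{\Delta R/R_k = (P_k - B) / B} for each post-stimulus bin image
#' \eqn{P_k} and baseline \eqn{B}, all on the filtered, downsampled grid.
#'
#' @param trial an [trial_stack()].
#' @param config an [acquisition_config()].
#' @param spec a [gaussian_spec()].
#' @param ds_method downsampling method, `"mean"` or `"decimate"`.
#' @return Object of class `iosi_drr`: list with `bins` (array
#'   `rows x cols x n_bins` of per-bin \eqn{\Delta R/R}), `n_bins` and
#'   `pixel_size_um`.
#' @export
drr_trial <- function(trial, config = acquisition_config(),
                      spec = gaussian_spec(), ds_method = "mean") {
  tm <- check_trial_timing(trial, config)
  proc <- filter_and_downsample(trial$frames, spec,
                                trial$calibration$downsample_factor,
                                ds_method)
  ptrial <- trial
  ptrial$frames <- proc
  drr_from_processed(ptrial, config,
                     analysis_pixel_size_um(trial$calibration))
}

# baseline/bins + ratio on an already filtered+downsampled stack
drr_from_processed <- function(ptrial, config, pixel_size_um) {
  B <- baseline_image(ptrial, config)
  if (any(B == 0)) {
    bad <- which(B == 0, arr.ind = TRUE)[1, ]
    stop("drr_trial: baseline reflectance is zero at pixel (row ",
         bad[1] - 1, ", col ", bad[2] - 1, ") of the analysis grid")
  }
  bins <- poststim_bins(ptrial, config)
  arr <- vapply(bins, function(P) (P - B) / B,
                matrix(0, nrow(B), ncol(B)))
  structure(list(bins = arr, n_bins = length(bins),
                 pixel_size_um = pixel_size_um),
            class = "iosi_drr")
}

evoked_map_object <- function(values, n_trials_used, pixel_size_um,
                              mask = NULL, window = NULL) {
  structure(list(values = values, n_trials_used = n_trials_used,
                 pixel_size_um = pixel_size_um, mask = mask,
                 window = window),
            class = "iosi_evoked_map")
}

#' Total stimulus-evoked delta-R/R map of a session
#'
#' Averages the per-trial \eqn{\Delta R/R} bins across the selected trials
#' and sums across bins, yielding a single total evoked image (mean over
#' trials, then sum over the five default bins; by linearity this equals
#' sum-then-mean).
#'
#' @param sess an [session()], or a list of `iosi_drr` objects.
#' @param trials integer vector selecting trials (default: all).
#' @param ... passed to [drr_trial()] (e.g. `spec`, `ds_method`).
#' @return An object of class `iosi_evoked_map`: `values` (matrix on the
#'   analysis grid), `n_trials_used`, `pixel_size_um`.
#' @export
evoked_map <- function(sess, trials = NULL, ...) {
  if (inherits(sess, "iosi_session")) {
    if (is.null(trials)) trials <- seq_along(sess$trials)
    if (length(trials) < 1L) stop("evoked_map: empty trial selection")
    drrs <- lapply(sess$trials[trials], drr_trial, config = sess$config, ...)
  } else {
    drrs <- if (is.null(trials)) sess else sess[trials]
    if (length(drrs) < 1L) stop("evoked_map: empty trial selection")
  }
  acc <- drrs[[1]]$bins
  if (length(drrs) > 1)
    for (i in 2:length(drrs)) acc <- acc + drrs[[i]]$bins
  acc <- acc / length(drrs)
  values <- rowSums(acc, dims = 2)
  m <- evoked_map_object(values, length(drrs), drrs[[1]]$pixel_size_um)
  if (inherits(sess, "iosi_session") && !is.null(sess$window)) {
    m <- apply_window_mask(m, c(sess$window$center_row, sess$window$center_col),
                           sess$window$radius_px)
  }
  m
}

#' @export
print.iosi_evoked_map <- function(x, ...) {
  cat(sprintf("IOSI evoked map: %d x %d analysis px (%g um), %d trial(s)\n",
              nrow(x$values), ncol(x$values), x$pixel_size_um,
              x$n_trials_used))
  cat(sprintf("  delta-R/R range: [%.3g, %.3g]%s\n", min(x$values),
              max(x$values),
              if (is.null(x$mask)) "" else " (window mask applied)"))
  invisible(x)
}

#' @export
plot.iosi_evoked_map <- function(x, ...) {
  # row 0 at the top, matching image coordinates
  v <- t(x$values[nrow(x$values):1, , drop = FALSE])
  image(v, col = gray(seq(0, 1, length.out = 256)), asp = 1,
        xaxt = "n", yaxt = "n", ...)
  invisible(x)
}
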