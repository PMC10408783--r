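#' Trial-accumulation curve of map area
#'
#' Quantifies how many trials are needed for a stable map: for each
#' `k = 1..n`, the evoked map over trials `1..k` is masked, thresholded,
#' median-cleaned and measured, and its area is expressed as a percent of
#' the all-trial (`k = n`) area.
#'
#' @param x an [session()], or a phantom configuration
#'   (see [phantom_config()]) from which trials are synthesized one at a
#'   time (memory-light for large simulated sessions).
#' @param spec an [threshold_spec()].
#' @param config acquisition config (only used for phantom input).
#' @param clean apply [clean_map()] before measuring (default `TRUE`).
#' @param ... passed to [drr_trial()].
#' @return Data frame with `k`, `area_mm2` and `percent_of_max` (100 at
#'   `k = n` by construction). Errors if the all-trial area is zero.
#' @export
trial_accumulation_curve <- function(x, spec = threshold_spec(),
                                     config = acquisition_config(),
                                     clean = TRUE, ...) {
  if (inherits(x, "iosi_session")) {
    n <- length(x$trials)
    if (n < 2L) stop("trial_accumulation_curve: need at least two trials")
    drrs <- lapply(x$trials, drr_trial, config = x$config, ...)
    window <- x$window
    pcal <- x$trials[[1]]$calibration
  } else if (inherits(x, "iosi_phantom_config")) {
    n <- x$n_trials
    if (n < 2L) stop("trial_accumulation_curve: need at least two trials")
    drrs <- phantom_drr_trials(x, config, ...)
    window <- phantom_window(x)
    pcal <- x$calibration
  } else stop("trial_accumulation_curve: unsupported input")
  areas <- numeric(n)
  acc <- 0
  for (k in seq_len(n)) {
    acc <- acc + drrs[[k]]$bins
    values <- rowSums(acc / k, dims = 2)
    m <- evoked_map_object(values, k, drrs[[k]]$pixel_size_um)
    if (!is.null(window))
      m <- apply_window_mask(m, c(window$center_row, window$center_col),
                             window$radius_px)
    b <- threshold_map(m, spec)
    if (clean) b <- clean_map(b)
    areas[k] <- map_area(b)
  }
  if (areas[n] <= 0)
    stop("trial_accumulation_curve: zero area with all ", n,
         " trials; percent-of-max undefined")
  # divide before scaling so the k = n entry is exactly 100
  data.frame(k = seq_len(n), area_mm2 = areas,
             percent_of_max = 100 * (areas / areas[n]))
}
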