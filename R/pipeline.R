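# End-to-end orchestration: process a session directory (or in-memory
# session) through filter -> downsample -> delta-R/R -> average/sum ->
# mask -> threshold -> clean -> overlay -> quantify, writing outputs and a
# run manifest sufficient to re-run identically.

PIPELINE_VERSION <- "0.1.0"

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "': ", conditionMessage(e),
         call. = FALSE))
}

#' Process an IOSI session end to end
#'
#' Computes the trial-averaged evoked \eqn{\Delta R/R} map, applies the
#' cranial-window mask, thresholds and median-cleans it into a binary
#' activation map, fits the moment ellipse, and (when requested) writes
#' the evoked map (float TIFF + JSON sidecar), binary map, vasculature
#' overlay, a quantification CSV and a run manifest into `out_dir`.
#'
#' @param sess an [session()] or a session directory path.
#' @param out_dir output directory, or `NULL` for no files.
#' @param spec an [threshold_spec()].
#' @param gaussian a [gaussian_spec()].
#' @param overlay_color color for the overlay painting.
#' @param clean apply the 3x3 median clean before quantification.
#' @param overlay write a vasculature overlay (requires a vasculature
#'   image; errors if requested without one).
#' @param force overwrite existing outputs.
#' @return List with `evoked` (`iosi_evoked_map`), `binary`
#'   (`iosi_binary_map`), `ellipse` (or `NULL` for an empty map),
#'   `area_mm2`, and `files` (paths written).
#' @export
process_session <- function(sess, out_dir = NULL,
                            spec = threshold_spec(),
                            gaussian = gaussian_spec(),
                            overlay_color = "yellow",
                            clean = TRUE, overlay = !is.null(out_dir),
                            force = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  input_files <- character(0)
  if (is.character(sess)) {
    input_files <- list.files(sess, full.names = TRUE)
    sess <- run_stage("read_session", read_session(sess))
  }
  timings <- c(read = proc.time()[["elapsed"]] - t0)
  if (overlay && is.null(sess$vasculature))
    stop("process_session: overlay requested but the session has no ",
         "vasculature image")
  t0 <- proc.time()[["elapsed"]]
  ev <- run_stage("evoked_map", evoked_map(sess, spec = gaussian))
  timings["evoked_map"] <- proc.time()[["elapsed"]] - t0
  t0 <- proc.time()[["elapsed"]]
  bm <- run_stage("threshold", threshold_map(ev, spec))
  if (clean) bm <- run_stage("clean", clean_map(bm))
  ell <- if (sum(bm$mask) >= 3)
    run_stage("fit_ellipse", fit_ellipse(bm)) else NULL
  area <- map_area(bm)
  timings["quantify"] <- proc.time()[["elapsed"]] - t0
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(out_dir, c("evoked.tif", "binary_map.tif",
                                  "overlay.png", "quantification.csv",
                                  "manifest.json"))
    names(paths) <- c("evoked", "binary", "overlay", "csv", "manifest")
    if (!force && any(file.exists(paths)))
      stop("process_session: outputs exist in ", out_dir,
           " (use force = TRUE)")
    t0 <- proc.time()[["elapsed"]]
    run_stage("write_evoked", write_evoked_map(ev, paths["evoked"]))
    run_stage("write_binary", {
      tiff::writeTIFF(bm$mask * 255 / 65535, paths["binary"],
                      bits.per.sample = 16L)
      jsonlite::write_json(bm$threshold_record,
                           paste0(paths[["binary"]], ".json"),
                           auto_unbox = TRUE, digits = NA)
    })
    files <- paths[c("evoked", "binary", "csv")]
    if (overlay) {
      rgbimg <- run_stage("overlay",
                          overlay_maps(list(bm), overlay_color,
                                       sess$vasculature))
      write_overlay(rgbimg, paths["overlay"])
      files <- c(files, paths["overlay"])
    }
    qdf <- data.frame(
      n_trials = ev$n_trials_used,
      area_mm2 = area,
      threshold_mode = bm$threshold_record$mode,
      cutoff_drr = bm$threshold_record$cutoff_drr,
      center_row = if (is.null(ell)) NA else ell$center[["row"]],
      center_col = if (is.null(ell)) NA else ell$center[["col"]],
      semi_major_um = if (is.null(ell)) NA else ell$semi_major_um,
      semi_minor_um = if (is.null(ell)) NA else ell$semi_minor_um,
      angle_rad = if (is.null(ell)) NA else ell$angle_rad
    )
    write.csv(qdf, paths["csv"], row.names = FALSE)
    timings["write"] <- proc.time()[["elapsed"]] - t0
    write_manifest(paths[["manifest"]], input_files, files, timings,
                   config = list(acquisition = unclass(sess$config),
                                 window = sess$window,
                                 threshold = unclass(spec),
                                 gaussian_sigma = gaussian$sigma,
                                 clean = clean))
    files <- c(files, paths["manifest"])
  }
  list(evoked = ev, binary = bm, ellipse = ell, area_mm2 = area,
       files = files)
}

# manifest written atomically (tempfile + rename): config snapshot, input
# hashes, package version, per-stage timings, outputs
write_manifest <- function(path, inputs, outputs, timings, config) {
  man <- list(
    package = "iosimap",
    version = PIPELINE_VERSION,
    config = config,
    inputs = if (length(inputs))
      data.frame(path = inputs, md5 = unname(tools::md5sum(inputs)))
    else NULL,
    outputs = unname(outputs),
    timings_s = as.list(round(timings, 3)),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(man, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  file.rename(tmp, path)
  invisible(path)
}

#' Integer-pixel alignment of two images by cross-correlation
#'
#' Finds the integer translation maximizing the normalized
#' cross-correlation of two mean-subtracted images (FFT-based), typically
#' two sessions' vasculature references.
#'
#' @param reference,moving numeric matrices of identical dimensions.
#' @param max_shift_px largest allowed shift along each axis.
#' @return `c(dr, dc)`: shift to apply to `moving` (via translation) to
#'   align it onto `reference`.
#' @export
align_by_vasculature <- function(reference, moving, max_shift_px = 32L) {
  if (!identical(dim(reference), dim(moving)))
    stop("align_by_vasculature: images differ in shape")
  a <- reference - mean(reference)
  b <- moving - mean(moving)
  n <- nrow(a); m <- ncol(a)
  # circular cross-correlation via FFT; restrict to modest shifts
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  shifts_r <- c(0:(n - 1)); shifts_r[shifts_r > n / 2] <- shifts_r[shifts_r > n / 2] - n
  shifts_c <- c(0:(m - 1)); shifts_c[shifts_c > m / 2] <- shifts_c[shifts_c > m / 2] - m
  ok <- outer(abs(shifts_r) <= max_shift_px, abs(shifts_c) <= max_shift_px)
  cc[!ok] <- -Inf
  best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  c(dr = shifts_r[best[1]], dc = shifts_c[best[2]])
}

#' Compare two longitudinal sessions (map plasticity)
#'
#' Aligns the post session onto the pre session by vasculature
#' cross-correlation (integer-pixel translation), processes both through
#' the standard pipeline, translates the post binary map onto the pre
#' grid, and reports both areas, the percent change, and (for lists of
#' session pairs, via [area_change()]) the paired t test.
#'
#' @param pre,post [session()] objects or session directory paths.
#' @param spec an [threshold_spec()].
#' @param ... passed to [process_session()].
#' @return List with `shift` (`c(dr, dc)` raw px), `pre`, `post`
#'   (processed results), `area_pre_mm2`, `area_post_mm2`,
#'   `percent_change`, `merged` (list of the two aligned binary maps).
#' @export
compare_sessions <- function(pre, post, spec = threshold_spec(), ...) {
  if (is.character(pre)) pre <- read_session(pre)
  if (is.character(post)) post <- read_session(post)
  if (is.null(pre$vasculature) || is.null(post$vasculature))
    stop("compare_sessions: both sessions need vasculature images for ",
         "alignment")
  shift_raw <- align_by_vasculature(pre$vasculature, post$vasculature)
  rp <- process_session(pre, out_dir = NULL, spec = spec, ...)
  pp <- process_session(post, out_dir = NULL, spec = spec, ...)
  f <- pre$trials[[1]]$calibration$downsample_factor
  shift_a <- round(shift_raw / f)
  aligned <- pp$binary
  sh <- shift_matrix(pp$binary$mask * 1, shift_a[1], shift_a[2])
  aligned$mask <- !is.na(sh) & sh > 0
  a_pre <- rp$area_mm2; a_post <- map_area(aligned)
  list(shift = shift_raw,
       pre = rp, post = pp, post_aligned = aligned,
       area_pre_mm2 = a_pre, area_post_mm2 = a_post,
       percent_change = 100 * (a_post - a_pre) / a_pre,
       merged = list(pre = rp$binary, post = aligned))
}
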