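#' Imaging session
#'
#' An ordered set of identically shaped trials plus the session's
#' vasculature reference image, cranial-window mask specification and
#' acquisition configuration.
#'
#' @param trials list of [trial_stack()] objects sharing dimensions, onset
#'   and calibration.
#' @param vasculature numeric matrix with the trials' raw dimensions, or
#'   `NULL`.
#' @param config an [acquisition_config()].
#' @param window circular cranial-window mask in analysis-pixel
#'   coordinates: `list(center_row=, center_col=, radius_px=)` (0-based
#'   center), or `NULL` for no mask.
#' @return An object of class `iosi_session`.
#' @export
session <- function(trials, vasculature = NULL, config = acquisition_config(),
                    window = NULL) {
  if (length(trials) < 1L) stop("session: at least one trial required")
  d1 <- dim(trials[[1]]$frames)
  for (tr in trials) {
    if (!inherits(tr, "iosi_trial")) stop("session: trials must be trial_stack objects")
    if (!identical(dim(tr$frames), d1))
      stop("session: trials differ in dimensions")
    if (tr$onset_frame != trials[[1]]$onset_frame)
      stop("session: trials differ in onset_frame")
    if (!identical(unclass(tr$calibration), unclass(trials[[1]]$calibration)))
      stop("session: trials differ in calibration")
  }
  if (!is.null(vasculature) && !identical(dim(vasculature), d1[1:2]))
    stop("session: vasculature dimensions ", paste(dim(vasculature), collapse = "x"),
         " do not match trial frames ", paste(d1[1:2], collapse = "x"))
  structure(list(trials = trials, vasculature = vasculature,
                 config = config, window = window),
            class = "iosi_session")
}

#' @export
print.iosi_session <- function(x, ...) {
  d <- dim(x$trials[[1]]$frames)
  cat(sprintf("IOSI session: %d trials of %d x %d px x %d frames%s\n",
              length(x$trials), d[1], d[2], d[3],
              if (is.null(x$vasculature)) "" else ", with vasculature image"))
  if (!is.null(x$window))
    cat(sprintf("  window mask: center (%g, %g), radius %g analysis px\n",
                x$window$center_row, x$window$center_col, x$window$radius_px))
  print(x$config)
  invisible(x)
}

#' Read a session configuration file (YAML or JSON)
#'
#' The document mirrors the [acquisition_config()] and
#' [spatial_calibration()] field names under `acquisition:` and
#' `calibration:` keys, plus optional `window_mask:` (center_row,
#' center_col, radius_px in analysis pixels) and `onset_frame`. Absent
#' fields take the package defaults, so an empty document reproduces the
#' standard protocol.
#'
#' @param path config file path (`.yaml`/`.yml` or `.json`).
#' @return list with `acquisition`, `calibration`, `window`, `onset_frame`.
#' @export
read_session_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  acq_args <- raw$acquisition[names(raw$acquisition) %in%
                                names(formals(acquisition_config))]
  if (is.null(acq_args)) acq_args <- list()
  acq <- do.call(acquisition_config, acq_args)
  if (is.null(raw$calibration)) {
    cal <- spatial_calibration(5.5, 4, 1, 4)   # CCD at 4x, the reference setup
  } else {
    cal_args <- raw$calibration[names(raw$calibration) %in%
                                  names(formals(spatial_calibration))]
    cal <- do.call(spatial_calibration, cal_args)
  }
  onset <- raw$onset_frame
  if (is.null(onset))
    onset <- frames_per_window(acq, acq$pre_stim_s, "pre_stim_s")
  window <- NULL
  if (!is.null(raw$window_mask) && !identical(raw$window_mask, "none"))
    window <- list(center_row = raw$window_mask$center_row,
                   center_col = raw$window_mask$center_col,
                   radius_px = raw$window_mask$radius_px)
  list(acquisition = acq, calibration = cal, window = window,
       onset_frame = as.integer(onset))
}

#' Write a session configuration file (YAML or JSON)
#'
#' @param acquisition an [acquisition_config()].
#' @param calibration a [spatial_calibration()].
#' @param path output path (`.yaml`/`.yml` or `.json`).
#' @param window optional window-mask list (see [read_session_config()]).
#' @param onset_frame optional 0-based onset frame index.
#' @return `path`, invisibly.
#' @export
write_session_config <- function(acquisition, calibration, path,
                                 window = NULL, onset_frame = NULL) {
  doc <- list(acquisition = unclass(acquisition),
              calibration = unclass(calibration))
  if (!is.null(window)) doc$window_mask <- window
  if (!is.null(onset_frame)) doc$onset_frame <- as.integer(onset_frame)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}

#' Read a session directory
#'
#' Expects `config.yaml` (or `config.json`), trial movies named
#' `trial_*.tif` (sorted order = acquisition order) or a single
#' concatenated `trials.tif` that is split into fixed-length trials, and
#' optionally `vasculature.tif`/`.png`.
#'
#' @param dir session directory.
#' @return An [session()] object.
#' @export
read_session <- function(dir) {
  cfgs <- file.path(dir, c("config.yaml", "config.yml", "config.json"))
  cfg_path <- cfgs[file.exists(cfgs)][1]
  if (is.na(cfg_path)) stop("read_session: no config.yaml/json in ", dir)
  cfg <- read_session_config(cfg_path)
  files <- sort(list.files(dir, pattern = "^trial_.*\\.tiff?$",
                           full.names = TRUE))
  if (length(files) > 0) {
    trials <- lapply(files, read_trial_stack,
                     onset_frame = cfg$onset_frame,
                     calibration = cfg$calibration)
  } else {
    concat <- file.path(dir, "trials.tif")
    if (!file.exists(concat))
      stop("read_session: no trial_*.tif files or trials.tif in ", dir)
    big <- read_trial_stack(concat, cfg$onset_frame, cfg$calibration)
    len <- trial_frame_count(cfg$acquisition)
    ntr <- dim(big$frames)[3] %/% len
    if (ntr * len != dim(big$frames)[3])
      stop("read_session: concatenated stack length ", dim(big$frames)[3],
           " is not a multiple of the ", len, "-frame trial length")
    trials <- lapply(seq_len(ntr), function(i) {
      trial_stack(big$frames[, , ((i - 1) * len + 1):(i * len), drop = FALSE],
                  cfg$onset_frame, cfg$calibration)
    })
  }
  vfiles <- file.path(dir, c("vasculature.tif", "vasculature.tiff",
                             "vasculature.png"))
  vpath <- vfiles[file.exists(vfiles)][1]
  vasc <- if (!is.na(vpath)) read_image(vpath) else NULL
  session(trials, vasc, cfg$acquisition, cfg$window)
}

#' Write a session directory
#'
#' Inverse of [read_session()]: writes per-trial TIFFs, the vasculature
#' image and `config.yaml`.
#'
#' @param sess an [session()].
#' @param dir output directory (created if needed).
#' @param force overwrite existing trial files.
#' @return `dir`, invisibly.
#' @export
write_session <- function(sess, dir, force = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  existing <- list.files(dir, pattern = "^trial_.*\\.tiff?$")
  if (length(existing) && !force)
    stop("write_session: ", dir, " already contains trial files ",
         "(use force = TRUE to overwrite)")
  for (i in seq_along(sess$trials)) {
    write_trial_stack(sess$trials[[i]],
                      file.path(dir, sprintf("trial_%03d.tif", i)))
  }
  if (!is.null(sess$vasculature))
    write_image(round(sess$vasculature), file.path(dir, "vasculature.tif"))
  write_session_config(sess$config, sess$trials[[1]]$calibration,
                       file.path(dir, "config.yaml"),
                       window = sess$window,
                       onset_frame = sess$trials[[1]]$onset_frame)
  invisible(dir)
}
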