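# Movie and image I/O.
#
# Grayscale multi-page TIFF for movies, TIFF/PNG for single images.
# Integer movies are stored losslessly at 16 bits; non-integer movies are
# stored as 32-bit float with the fixed scale counts/65535 (the float TIFF
# payload must lie in [0, 1]).

COUNT_SCALE <- 65535

#' Read a trial movie from a multi-page TIFF
#'
#' Pages are read in acquisition order as floating-point reflectance counts.
#' Integer TIFFs (8/12/14/16 bit in 16-bit containers) are returned at
#' their stored integer values; 32-bit float TIFFs written by
#' [write_trial_stack()] are rescaled back to counts.
#'
#' @param path path to a single-channel multi-page TIFF.
#' @param onset_frame 0-based index of the first at/after-onset frame.
#' @param calibration a [spatial_calibration()].
#' @return An [trial_stack()] object.
#' @export
read_trial_stack <- function(path, onset_frame, calibration) {
  if (!file.exists(path))
    stop("read_trial_stack: file not found: ", path)
  info <- tiff::readTIFF(path, payload = FALSE, all = TRUE)
  if (is.null(nrow(info))) info <- as.data.frame(as.list(info))
  if (nrow(info) < onset_frame + 1)
    stop("read_trial_stack: ", path, " has ", nrow(info),
         " pages but onset_frame = ", onset_frame)
  if (any(info$samples.per.pixel > 1L))
    stop("read_trial_stack: ", path, " has multi-channel pages; ",
         "single-channel grayscale movies are required")
  is_float <- info$bits.per.sample[1] == 32L
  # integer TIFFs: original counts (as.is); float TIFFs: counts/COUNT_SCALE
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !is_float)
  if (!is.list(pages)) pages <- list(pages)
  arr <- simplify2array(pages)          # rows x cols x pages
  if (is_float) arr <- arr * COUNT_SCALE
  storage.mode(arr) <- "double"
  trial_stack(arr, onset_frame, calibration)
}

#' Write a trial movie as a multi-page TIFF
#'
#' Integer-valued stacks (all counts whole numbers below 65536) are written
#' as 16-bit integer pages and round-trip losslessly through
#' [read_trial_stack()]; other stacks are written as 32-bit float pages
#' holding counts/65535.
#'
#' @param stack an [trial_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial_stack <- function(stack, path) {
  fr <- stack$frames
  pages <- lapply(seq_len(dim(fr)[3]), function(t) fr[, , t])
  intlike <- max(fr) < COUNT_SCALE + 1 &&
    max(abs(fr - round(fr))) == 0
  if (intlike) {
    tiff::writeTIFF(lapply(pages, function(p) p / COUNT_SCALE), path,
                    bits.per.sample = 16L)
  } else {
    if (max(fr) > COUNT_SCALE)
      stop("write_trial_stack: counts exceed the storable range (65535)")
    tiff::writeTIFF(lapply(pages, function(p) p / COUNT_SCALE), path,
                    bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read a single grayscale image (TIFF or PNG)
#'
#' @param path image path; format chosen by extension.
#' @return Numeric matrix. TIFFs are returned at stored integer values;
#'   PNGs on their native 0–1 scale.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("read_image: file not found: ", path)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path, as.is = TRUE)
  }
  if (length(dim(img)) == 3L) {
    # collapse RGB(A) to grayscale by channel mean (vasculature reference
    # images are effectively single-channel)
    img <- apply(img[, , 1:min(3L, dim(img)[3]), drop = FALSE], c(1, 2), mean)
  }
  storage.mode(img) <- "double"
  img
}

#' Write a single grayscale image (TIFF or PNG)
#'
#' @param img numeric matrix of counts (TIFF, stored 16-bit) or of 0–1
#'   intensities (PNG).
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(pmin(pmax(img, 0), 1), path)
  } else {
    tiff::writeTIFF(img / COUNT_SCALE, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Write an evoked map as 32-bit float TIFF plus JSON provenance sidecar
#'
#' The TIFF stores the map affinely rescaled to `[0, 1]`; the sidecar
#' (`<path>.json`) records the affine transform together with provenance
#' (trials used, pixel size, mask), so [read_evoked_map()] restores the
#' original \eqn{\Delta R/R} values.
#'
#' @param map an `iosi_evoked_map` (see [evoked_map()]).
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_evoked_map <- function(map, path) {
  v <- map$values
  lo <- min(v); hi <- max(v)
  rng <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((v - lo) / rng, path, bits.per.sample = 32L)
  side <- list(
    value_min = lo, value_range = rng,
    n_trials_used = map$n_trials_used,
    pixel_size_um = map$pixel_size_um,
    window = map$window
  )
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an evoked map written by [write_evoked_map()]
#' @param path TIFF path (expects `<path>.json` sidecar alongside).
#' @return An `iosi_evoked_map`.
#' @export
read_evoked_map <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- tiff::readTIFF(path) * side$value_range + side$value_min
  m <- evoked_map_object(v, side$n_trials_used, side$pixel_size_um)
  if (!is.null(side$window) && length(side$window)) {
    m <- apply_window_mask(m, unlist(side$window[c("center_row", "center_col")]),
                           side$window$radius_px)
  }
  m
}
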