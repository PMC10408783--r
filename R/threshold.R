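#' Threshold specification for map binarization
#'
#' Two modes, matching how small and large cortical maps are binarized:
#' `"zscore"` marks pixels with z-scored \eqn{\Delta R/R} below `z_cut`
#' (default -3; evoked intrinsic signals are reflectance *decreases*, so
#' the cut is negative); `"percent_max"` marks pixels whose signal
#' magnitude \eqn{-\Delta R/R} reaches at least `percent` of the peak
#' magnitude.
#'
#' @param mode `"zscore"` or `"percent_max"`.
#' @param z_cut z-score threshold (< 0) for `"zscore"` mode.
#' @param percent fraction of the peak magnitude (0 < percent < 1) for
#'   `"percent_max"` mode. There is no canonical value; 0.5 is this
#'   package's default.
#' @param in_mask_only if `TRUE`, compute the z-score mean/sd over
#'   in-window pixels only, excluding the zeroed surround. The default
#'   (`FALSE`) computes them over the whole masked image, matching the
#'   reference MATLAB pipeline which z-scores the masked \eqn{\Delta R/R}
#'   image as-is; see the vignette for the tradeoff.
#' @return Object of class `iosi_threshold`.
#' @export
threshold_spec <- function(mode = c("zscore", "percent_max"), z_cut = -3,
                           percent = 0.5, in_mask_only = FALSE) {
  mode <- match.arg(mode)
  if (mode == "zscore" && z_cut >= 0)
    stop("threshold_spec: z_cut must be negative (evoked signal is a ",
         "reflectance decrease)")
  if (mode == "percent_max" && (percent <= 0 || percent >= 1))
    stop("threshold_spec: percent must be in (0, 1)")
  structure(list(mode = mode, z_cut = z_cut, percent = percent,
                 in_mask_only = in_mask_only),
            class = "iosi_threshold")
}

#' Z-score an evoked map
#'
#' Per-pixel `(value - mean) / sd` with the sample standard deviation
#' (denominator n-1). With `in_mask_only = FALSE` (default) the statistics
#' are computed over every pixel of the (masked) map, as the reference
#' pipeline does; with `TRUE` they are computed over in-window pixels only
#' and out-of-window pixels are assigned z = 0.
#'
#' @param map an `iosi_evoked_map`.
#' @param in_mask_only see [threshold_spec()].
#' @return Numeric matrix of z-scores.
#' @export
zscore_map <- function(map, in_mask_only = FALSE) {
  v <- map$values
  sel <- if (in_mask_only && !is.null(map$mask)) map$mask else
    !logical(length(v))
  if (sum(sel) < 2L) stop("zscore_map: fewer than two pixels available")
  mu <- mean(v[sel]); sg <- sd(v[sel])
  if (sg == 0) stop("zscore_map: zero variance across pixels")
  z <- (v - mu) / sg
  if (in_mask_only && !is.null(map$mask)) z[!map$mask] <- 0
  z
}

binary_map_object <- function(mask, pixel_size_um, record) {
  structure(list(mask = mask, pixel_size_um = pixel_size_um,
                 threshold_record = record),
            class = "iosi_binary_map")
}

#' Binarize an evoked map
#'
#' Applies the threshold rule of `spec` (see [threshold_spec()]):
#' z-score mode marks pixels with `z < z_cut`; percent-of-peak mode marks
#' pixels with \eqn{-\Delta R/R \ge} `percent` times the in-window peak
#' magnitude. Pixels outside the window mask are always `FALSE`. The
#' realized cutoff is recorded in \eqn{\Delta R/R} units.
#'
#' @param map an `iosi_evoked_map` (masked or not).
#' @param spec an [threshold_spec()].
#' @return An `iosi_binary_map`: logical `mask`, `pixel_size_um`, and
#'   `threshold_record` (the spec plus realized `cutoff_drr`).
#' @export
threshold_map <- function(map, spec = threshold_spec()) {
  v <- map$values
  inwin <- if (!is.null(map$mask)) map$mask else !logical(length(v))
  if (spec$mode == "zscore") {
    sel <- if (spec$in_mask_only) inwin else !logical(length(v))
    mu <- mean(v[sel]); sg <- sd(v[sel])
    if (sg == 0) stop("threshold_map: zero variance across pixels")
    hit <- (v - mu) / sg < spec$z_cut
    cutoff <- mu + spec$z_cut * sg
  } else {
    mag <- -v
    peak <- max(mag[inwin])
    if (peak <= 0)
      stop("threshold_map: no negative delta-R/R pixels inside the window; ",
           "percent_max thresholding undefined")
    hit <- mag >= spec$percent * peak
    cutoff <- -spec$percent * peak
  }
  hit <- hit & inwin
  rec <- c(unclass(spec), list(cutoff_drr = cutoff))
  binary_map_object(hit, map$pixel_size_um, rec)
}

#' Median-filter a binary map (3x3 majority vote)
#'
#' The 3x3 binary median filter used to remove isolated noise pixels
#' before area measurement: a pixel is `TRUE` iff at least 5 of the 9
#' pixels in its neighborhood are `TRUE`, with the border padded `FALSE`.
#' Ties are impossible in a 9-element window. Idempotent on large solid
#' regions; never creates `TRUE` pixels far from existing ones.
#'
#' @param bmap an `iosi_binary_map`.
#' @return The cleaned `iosi_binary_map`.
#' @export
clean_map <- function(bmap) {
  m <- bmap$mask
  n <- nrow(m); p <- ncol(m)
  padded <- matrix(0L, n + 2, p + 2)
  padded[2:(n + 1), 2:(p + 1)] <- m
  acc <- matrix(0L, n, p)
  for (dr in 0:2) for (dc in 0:2)
    acc <- acc + padded[(1 + dr):(n + dr), (1 + dc):(p + dc)]
  bmap$mask <- acc >= 5L
  bmap
}

#' @export
print.iosi_binary_map <- function(x, ...) {
  cat(sprintf("IOSI binary map: %d x %d px (%g um), %d active (%.3g mm^2)\n",
              nrow(x$mask), ncol(x$mask), x$pixel_size_um, sum(x$mask),
              map_area(x)))
  tr <- x$threshold_record
  if (!is.null(tr))
    cat(sprintf("  threshold: %s, realized cutoff %.3g delta-R/R\n",
                tr$mode, tr$cutoff_drr))
  invisible(x)
}

#' @export
plot.iosi_binary_map <- function(x, ...) {
  v <- t(x$mask[nrow(x$mask):1, , drop = FALSE]) * 1
  image(v, col = c("black", "white"), asp = 1, xaxt = "n", yaxt = "n", ...)
  invisible(x)
}
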