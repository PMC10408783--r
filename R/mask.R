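#' Circular pixel mask
#'
#' Logical matrix marking pixels whose center lies within `radius` of
#' `center` (Euclidean, `<= radius`). Coordinates are 0-based
#' `(row, col)`, row 0 at the image top.
#'
#' @param dims `c(rows, cols)`.
#' @param center numeric `(row, col)`, 0-based; may be fractional.
#' @param radius radius in pixels.
#' @return Logical matrix.
#' @export
circle_mask <- function(dims, center, radius) {
  r <- matrix(0:(dims[1] - 1), dims[1], dims[2])
  c_ <- matrix(0:(dims[2] - 1), dims[1], dims[2], byrow = TRUE)
  (r - center[1])^2 + (c_ - center[2])^2 <= radius^2
}

#' Best-effort automatic window circle from a vasculature image
#'
#' Estimates the cranial-window circle as the largest circle inscribed in
#' the above-background region of the vasculature image (background =
#' pixels below `frac` of the image maximum, e.g. the dark surround of the
#' window). This is a convenience for roughly centered, well-lit windows;
#' the user-supplied circle in the session config is always preferred and
#' remains the default.
#'
#' @param vasculature numeric matrix (raw or analysis grid).
#' @param frac background threshold as a fraction of the maximum.
#' @return `list(center_row, center_col, radius_px)`, 0-based, on the
#'   input grid.
#' @export
fit_window_circle <- function(vasculature, frac = 0.5) {
  fg <- vasculature >= frac * max(vasculature)
  if (!any(fg)) stop("fit_window_circle: no above-background pixels")
  idx <- which(fg, arr.ind = TRUE) - 1
  ctr <- colMeans(idx)
  bg <- which(!fg, arr.ind = TRUE) - 1
  r <- if (nrow(bg) == 0) {
    # window fills the frame: inscribe in the image rectangle
    min(ctr[1], ctr[2], nrow(vasculature) - 1 - ctr[1],
        ncol(vasculature) - 1 - ctr[2])
  } else {
    sqrt(min((bg[, 1] - ctr[1])^2 + (bg[, 2] - ctr[2])^2))
  }
  list(center_row = unname(ctr[1]), center_col = unname(ctr[2]),
       radius_px = r)
}

#' Apply a circular cranial-window mask to an evoked map
#'
#' Pixels outside the circle are set to 0; pixels inside are unchanged.
#' The mask is recorded on the returned map so downstream statistics
#' (z-scoring, percent-of-peak thresholds) can distinguish in-window
#' pixels from the zeroed surround.
#'
#' @param map an `iosi_evoked_map`.
#' @param center window center `(row, col)` in 0-based analysis pixels.
#' @param radius window radius in analysis pixels.
#' @return The masked `iosi_evoked_map`.
#' @export
apply_window_mask <- function(map, center, radius) {
  dims <- dim(map$values)
  if (center[1] + radius < 0 || center[1] - radius > dims[1] - 1 ||
      center[2] + radius < 0 || center[2] - radius > dims[2] - 1)
    stop("apply_window_mask: circle lies entirely outside the image")
  inside <- circle_mask(dims, center, radius)
  if (!any(inside))
    warning("apply_window_mask: mask contains no pixels")
  map$values[!inside] <- 0
  map$mask <- inside
  map$window <- list(center_row = center[1], center_col = center[2],
                     radius_px = radius)
  map
}
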