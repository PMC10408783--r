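#' Area of a binary map
#'
#' True-pixel count times the squared analysis pixel size:
#' `n * (pixel_size_um * 1e-3)^2` square millimetres. An empty map has
#' area 0.
#'
#' @param bmap an `iosi_binary_map`.
#' @return Area in mm^2.
#' @export
map_area <- function(bmap) {
  if (is.null(bmap$pixel_size_um))
    stop("map_area: pixel size not set on this map")
  sum(bmap$mask) * (bmap$pixel_size_um * 1e-3)^2
}

# 4-connected component labeling (iterative flood fill)
label_components <- function(mask) {
  n <- nrow(mask); p <- ncol(mask)
  lab <- matrix(0L, n, p)
  cur <- 0L
  idx <- which(mask)
  stack <- integer(length(idx))
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    top <- 1L
    stack[1L] <- start
    lab[start] <- cur
    while (top > 0L) {
      s <- stack[top]; top <- top - 1L
      r <- ((s - 1L) %% n) + 1L
      cfull <- ((s - 1L) %/% n) + 1L
      for (nb in c(if (r > 1L) s - 1L,
                   if (r < n) s + 1L,
                   if (cfull > 1L) s - n,
                   if (cfull < p) s + n)) {
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- cur
          top <- top + 1L
          stack[top] <- nb
        }
      }
    }
  }
  lab
}

#' Moment-matched ellipse fit of a binary map
#'
#' Fits the ellipse whose center is the pixel centroid and whose axes and
#' orientation derive from the 2x2 central second-moment matrix of the
#' true pixels, scaled so the ellipse area equals the pixel area — the
#' ImageJ "Analyze Particles" fit-ellipse convention. Second moments
#' include the 1/12 per-pixel term so a filled `w x h` rectangle yields an
#' exact `w : h` axis ratio.
#'
#' When the map has several connected components the largest by pixel
#' count is fitted (set `largest_component = FALSE` to fit all pixels).
#'
#' @param bmap an `iosi_binary_map` with at least 3 true pixels.
#' @param largest_component restrict the fit to the largest 4-connected
#'   component (default `TRUE`).
#' @return Object of class `iosi_ellipse`: `center` (0-based
#'   `(row, col)` analysis pixels), `semi_major_um`, `semi_minor_um`,
#'   `angle_rad` (major-axis angle from the +column axis, rows increasing
#'   downward), `n_pixels`, `pixel_size_um`.
#' @export
fit_ellipse <- function(bmap, largest_component = TRUE) {
  m <- bmap$mask
  if (largest_component && any(m)) {
    lab <- label_components(m)
    sizes <- tabulate(lab[lab > 0L])
    m <- lab == which.max(sizes)
  }
  idx <- which(m, arr.ind = TRUE)
  n <- nrow(idx)
  if (n < 3L) stop("fit_ellipse: need at least 3 true pixels")
  y <- idx[, 1] - 1  # 0-based rows
  x <- idx[, 2] - 1  # 0-based cols
  xb <- mean(x); yb <- mean(y)
  uxx <- mean((x - xb)^2) + 1 / 12
  uyy <- mean((y - yb)^2) + 1 / 12
  uxy <- mean((x - xb) * (y - yb))
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  l1 <- (uxx + uyy + common) / 2
  l2 <- (uxx + uyy - common) / 2
  if (l2 <= 0) stop("fit_ellipse: degenerate (collinear) pixel set")
  a0 <- 2 * sqrt(l1); b0 <- 2 * sqrt(l2)
  scale <- sqrt(n / (pi * a0 * b0))   # match ellipse area to pixel area
  angle <- 0.5 * atan2(2 * uxy, uxx - uyy)
  px <- bmap$pixel_size_um
  structure(list(center = c(row = yb, col = xb),
                 semi_major_um = a0 * scale * px,
                 semi_minor_um = b0 * scale * px,
                 angle_rad = angle,
                 n_pixels = n,
                 pixel_size_um = px),
            class = "iosi_ellipse")
}

#' @export
print.iosi_ellipse <- function(x, ...) {
  cat(sprintf(
    "Moment ellipse: center (row %.2f, col %.2f) px, semi-axes %.1f x %.1f um, angle %.1f deg, %d px\n",
    x$center[1], x$center[2], x$semi_major_um, x$semi_minor_um,
    x$angle_rad * 180 / pi, x$n_pixels))
  invisible(x)
}

#' Center displacement between two ellipse fits
#'
#' `(map center - reference center)` converted to micrometres. Sign
#' convention: +x rightward (increasing column), +y downward (increasing
#' row).
#'
#' @param map_fit,reference_fit [fit_ellipse()] results on the same grid.
#' @param pixel_size_um analysis pixel size; defaults to the fits' own.
#' @return Named numeric `c(dx_um, dy_um)`.
#' @export
displacement <- function(map_fit, reference_fit,
                         pixel_size_um = map_fit$pixel_size_um) {
  if (!isTRUE(all.equal(map_fit$pixel_size_um,
                        reference_fit$pixel_size_um)))
    stop("displacement: fits are on different grids")
  c(dx_um = (map_fit$center[["col"]] - reference_fit$center[["col"]]) *
      pixel_size_um,
    dy_um = (map_fit$center[["row"]] - reference_fit$center[["row"]]) *
      pixel_size_um)
}
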