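#' Overlay binary maps on a vasculature image
#'
#' Builds an 8-bit RGB image: the vasculature rescaled to 0–255 grayscale,
#' with each binary map painted in its color at the given opacity.
#' Where maps overlap, their color contributions add and the result is
#' clipped to 255.
#'
#' @param maps list of `iosi_binary_map` objects sharing dimensions.
#' @param colors vector of R color names or hex strings, one per map.
#' @param vasculature numeric matrix; resampled by block mean to the maps'
#'   analysis grid if larger.
#' @param opacity blending opacity in `[0, 1]` (1 = solid color).
#' @return Numeric array `rows x cols x 3` of 8-bit values (0–255).
#' @export
overlay_maps <- function(maps, colors, vasculature, opacity = 0.6) {
  if (length(maps) != length(colors))
    stop("overlay_maps: need one color per map")
  d <- dim(maps[[1]]$mask)
  for (m in maps)
    if (!identical(dim(m$mask), d))
      stop("overlay_maps: maps differ in shape")
  if (is.null(vasculature))
    stop("overlay_maps: vasculature image required for overlay")
  if (!identical(dim(vasculature), d)) {
    f <- unique(dim(vasculature) %/% d)
    if (length(f) != 1L || any(dim(vasculature) != d * f))
      stop("overlay_maps: vasculature shape ",
           paste(dim(vasculature), collapse = "x"),
           " is not an integer multiple of the map grid ",
           paste(d, collapse = "x"))
    vasculature <- downsample(vasculature, f)
  }
  rng <- range(vasculature)
  g <- if (rng[2] > rng[1])
    (vasculature - rng[1]) / (rng[2] - rng[1]) * 255 else
      matrix(127.5, d[1], d[2])
  out <- array(0, c(d, 3L))
  any_map <- Reduce(`|`, lapply(maps, `[[`, "mask"))
  for (ch in 1:3) out[, , ch] <- g * (1 - opacity * any_map)
  for (i in seq_along(maps)) {
    rgb <- col2rgb(colors[i])[, 1]
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[maps[[i]]$mask] <- plane[maps[[i]]$mask] +
        opacity * rgb[ch]
      out[, , ch] <- plane
    }
  }
  pmin(pmax(out, 0), 255)
}

#' Write an RGB overlay as an 8-bit PNG
#' @param rgb numeric array `rows x cols x 3` of 0–255 values.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(rgb, path) {
  png::writePNG(rgb / 255, path)
  invisible(path)
}

#' Group-average evoked maps after center alignment
#'
#' Translates each map by an integer pixel offset bringing its reference
#' center (typically the fitted ellipse center of a reference area) to the
#' common grid center, averages pixelwise over the contributing maps
#' (pixels covered by no map after translation are excluded), and linearly
#' rescales the mean to 8-bit 0–255. A constant mean image maps to 0.
#'
#' @param maps list of `iosi_evoked_map` objects sharing dimensions.
#' @param reference_centers list/matrix of `(row, col)` centers (0-based
#'   analysis pixels), one per map.
#' @return An `iosi_evoked_map` whose `values` are the 0–255 rescaled
#'   average.
#' @export
group_average <- function(maps, reference_centers) {
  if (length(maps) < 1L) stop("group_average: empty map list")
  if (is.list(reference_centers))
    reference_centers <- do.call(rbind, reference_centers)
  reference_centers <- matrix(reference_centers, ncol = 2)
  if (nrow(reference_centers) != length(maps))
    stop("group_average: need one reference center per map")
  d <- dim(maps[[1]]$values)
  target <- floor((d - 1) / 2)                  # 0-based grid center
  acc <- matrix(0, d[1], d[2])
  cnt <- matrix(0L, d[1], d[2])
  for (i in seq_along(maps)) {
    v <- maps[[i]]$values
    if (!identical(dim(v), d)) stop("group_average: maps differ in shape")
    sh <- round(target - reference_centers[i, ])  # integer translation
    tr <- shift_matrix(v, sh[1], sh[2])
    ok <- !is.na(tr)
    acc[ok] <- acc[ok] + tr[ok]
    cnt[ok] <- cnt[ok] + 1L
  }
  covered <- cnt > 0L
  avg <- matrix(NA_real_, d[1], d[2])
  avg[covered] <- acc[covered] / cnt[covered]
  rng <- range(avg[covered])
  out <- matrix(0, d[1], d[2])
  if (rng[2] > rng[1])
    out[covered] <- (avg[covered] - rng[1]) / (rng[2] - rng[1]) * 255
  evoked_map_object(out, length(maps), maps[[1]]$pixel_size_um)
}

# integer translation; vacated pixels become NA
shift_matrix <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(NA_real_, n, p)
  src_r <- seq_len(n) - dr
  src_c <- seq_len(p) - dc
  ok_r <- src_r >= 1 & src_r <= n
  ok_c <- src_c >= 1 & src_c <= p
  out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}
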