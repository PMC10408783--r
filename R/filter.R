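#' Gaussian spatial filter specification
#'
#' The pipeline's pre-filter: a 2-D Gaussian of standard deviation `sigma`
#' (raw pixels) with kernel size `2*ceil(2*sigma) + 1`, the MATLAB
#' `imgaussfilt` default. Weights are normalized to sum to one; the default
#' `sigma = 0.5` yields a 3x3 kernel.
#'
#' @param sigma Gaussian sigma in raw pixels (> 0).
#' @return Object of class `iosi_gaussian` with fields `sigma`,
#'   `kernel_size`, and the normalized 1-D `weights` of the separable
#'   kernel.
#' @examples
#' gaussian_spec(0.5)$kernel_size  # 3
#' @export
gaussian_spec <- function(sigma = 0.5) {
  if (!is.numeric(sigma) || sigma <= 0) stop("gaussian_spec: sigma must be > 0")
  size <- 2L * as.integer(ceiling(2 * sigma)) + 1L
  half <- (size - 1L) / 2L
  w <- exp(-((-half):half)^2 / (2 * sigma^2))
  structure(list(sigma = sigma, kernel_size = size, weights = w / sum(w)),
            class = "iosi_gaussian")
}

#' Gaussian-filter every frame of a trial
#'
#' Convolves each frame independently (purely spatial, no temporal
#' smoothing) with the normalized separable Gaussian kernel; image borders
#' are handled by edge replication, which preserves constant frames
#' exactly.
#'
#' @param stack an [trial_stack()].
#' @param spec a [gaussian_spec()].
#' @return A filtered [trial_stack()] of identical shape.
#' @export
gaussian_filter_frames <- function(stack, spec = gaussian_spec()) {
  out <- stack
  out$frames <- cpp_sep_filter(stack$frames, spec$weights)
  out
}

#' Gaussian-filter a single image
#' @param img numeric matrix.
#' @param spec a [gaussian_spec()].
#' @return Filtered matrix.
#' @export
gaussian_filter_image <- function(img, spec = gaussian_spec()) {
  dim(img) <- c(dim(img), 1L)
  cpp_sep_filter(img, spec$weights)[, , 1]
}

#' Spatially downsample by block averaging
#'
#' Non-overlapping `factor x factor` block means (the default) or
#' decimation (top-left pixel of each block). Output dimensions are
#' `floor(dim/factor)`; trailing partial blocks are dropped. For trial
#' stacks the operation applies to every frame; the calibration's
#' downsample factor describes the resulting analysis grid.
#'
#' @param x numeric matrix or [trial_stack()].
#' @param factor integer >= 1.
#' @param method `"mean"` (block mean, default) or `"decimate"`.
#' @return Same kind as `x`, downsampled.
#' @export
downsample <- function(x, factor, method = c("mean", "decimate")) {
  UseMethod("downsample")
}

check_ds_factor <- function(d, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("downsample: factor must be >= 1")
  if (factor > d[1] || factor > d[2])
    stop("downsample: factor ", factor, " exceeds image dimensions ",
         d[1], " x ", d[2])
  factor
}

#' @export
downsample.matrix <- function(x, factor, method = c("mean", "decimate")) {
  method <- match.arg(method)
  factor <- check_ds_factor(dim(x), factor)
  if (factor == 1L) return(x)
  n <- nrow(x) %/% factor; m <- ncol(x) %/% factor
  x <- x[seq_len(n * factor), seq_len(m * factor), drop = FALSE]
  if (method == "decimate")
    return(x[seq(1, n * factor, by = factor), seq(1, m * factor, by = factor),
             drop = FALSE])
  dim(x) <- c(dim(x), 1L)
  res <- cpp_block_mean(x, factor)
  matrix(res, dim(res)[1], dim(res)[2])
}

#' @export
downsample.array <- function(x, factor, method = c("mean", "decimate")) {
  method <- match.arg(method)
  factor <- check_ds_factor(dim(x), factor)
  if (factor == 1L) return(x)
  n <- dim(x)[1] %/% factor; m <- dim(x)[2] %/% factor
  x <- x[seq_len(n * factor), seq_len(m * factor), , drop = FALSE]
  if (method == "decimate")
    return(x[seq(1, n * factor, by = factor), seq(1, m * factor, by = factor), ,
             drop = FALSE])
  cpp_block_mean(x, factor)
}

#' @export
downsample.iosi_trial <- function(x, factor = x$calibration$downsample_factor,
                                  method = c("mean", "decimate")) {
  out <- x
  out$frames <- downsample.array(x$frames, factor, method)
  out
}

# fused filter + block mean used by the delta-R/R pipeline; numerically
# equal (to rounding) to gaussian_filter then downsample, but one pass
filter_and_downsample <- function(frames, spec, factor,
                                  method = c("mean", "decimate")) {
  method <- match.arg(method)
  factor <- check_ds_factor(dim(frames), factor)
  n <- dim(frames)[1] %/% factor; m <- dim(frames)[2] %/% factor
  if (n * factor != dim(frames)[1] || m * factor != dim(frames)[2])
    frames <- frames[seq_len(n * factor), seq_len(m * factor), , drop = FALSE]
  if (method == "mean" && factor > 1L)
    return(cpp_filter_block(frames, spec$weights, factor))
  out <- cpp_sep_filter(frames, spec$weights)
  if (factor > 1L)
    out <- out[seq(1, n * factor, by = factor),
               seq(1, m * factor, by = factor), , drop = FALSE]
  out
}
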