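# Brute-force reference implementations and small fixture builders used
# across the suite. Oracles are deliberately written in the most naive
# style (explicit loops / double sums) and share no code with the package
# internals they check.

# small, fast phantom for property tests (geometry need not match defaults)
small_phantom <- function(image_size = c(64, 64), blob_sigma_um = 160,
                          n_trials = 3, seed = 11, ...) {
  phantom_config(image_size = image_size,
                 calibration = spatial_calibration(33, 4, 1, 4),
                 blob_sigma_um = blob_sigma_um, n_trials = n_trials,
                 seed = seed, ...)
}

# a trial whose frame t (0-based) is constant at value t, for timing oracles
index_trial <- function(n_frames = 40, onset = 10, dims = c(8, 8),
                        cal = spatial_calibration(22, 1, 1, 1)) {
  fr <- array(rep(0:(n_frames - 1), each = prod(dims)),
              c(dims, n_frames))
  trial_stack(fr, onset, cal)
}

# naive block mean with trailing-block cropping
oracle_block_mean <- function(m, f) {
  n <- nrow(m) %/% f; p <- ncol(m) %/% f
  out <- matrix(0, n, p)
  for (i in seq_len(n)) for (j in seq_len(p)) {
    out[i, j] <- mean(m[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)])
  }
  out
}

# naive 2-D convolution with edge replication
oracle_gauss_filter <- function(m, w1d) {
  h <- (length(w1d) - 1) / 2
  k2 <- outer(w1d, w1d)
  n <- nrow(m); p <- ncol(m)
  out <- matrix(0, n, p)
  for (i in seq_len(n)) for (j in seq_len(p)) {
    acc <- 0
    for (di in -h:h) for (dj in -h:h) {
      ii <- min(max(i + di, 1), n)
      jj <- min(max(j + dj, 1), p)
      acc <- acc + k2[di + h + 1, dj + h + 1] * m[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# naive 3x3 binary majority vote with FALSE padding
oracle_median3 <- function(m) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(FALSE, n, p)
  for (i in seq_len(n)) for (j in seq_len(p)) {
    cnt <- 0
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= n && jj >= 1 && jj <= p && m[ii, jj])
        cnt <- cnt + 1
    }
    out[i, j] <- cnt >= 5
  }
  out
}

# naive circular mask by per-pixel distance test (0-based coords)
oracle_circle <- function(dims, center, radius) {
  out <- matrix(FALSE, dims[1], dims[2])
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    out[i, j] <- sqrt((i - 1 - center[1])^2 + (j - 1 - center[2])^2) <= radius
  }
  out
}

# naive central image moments (explicit double sum over true pixels)
oracle_moments <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  y <- idx[, 1] - 1; x <- idx[, 2] - 1
  n <- length(x)
  xb <- sum(x) / n; yb <- sum(y) / n
  uxx <- 0; uyy <- 0; uxy <- 0
  for (k in seq_len(n)) {
    uxx <- uxx + (x[k] - xb)^2
    uyy <- uyy + (y[k] - yb)^2
    uxy <- uxy + (x[k] - xb) * (y[k] - yb)
  }
  list(n = n, xb = xb, yb = yb,
       uxx = uxx / n + 1 / 12, uyy = uyy / n + 1 / 12, uxy = uxy / n)
}

# closed-form two-sample Hotelling T^2 (2-D), exact-F p-value
oracle_hotelling <- function(g1, g2) {
  n1 <- nrow(g1); n2 <- nrow(g2); p <- 2
  d <- colMeans(g1) - colMeans(g2)
  S <- ((n1 - 1) * stats::cov(g1) + (n2 - 1) * stats::cov(g2)) / (n1 + n2 - 2)
  t2 <- (n1 * n2 / (n1 + n2)) * drop(t(d) %*% solve(S) %*% d)
  f <- (n1 + n2 - p - 1) / ((n1 + n2 - 2) * p) * t2
  stats::pf(f, p, n1 + n2 - 1 - p, lower.tail = FALSE)
}

# random binary blob (ellipse-ish region plus salt) on a g x g grid
random_blob <- function(g = 32, seed = 1) {
  set.seed(seed)
  ctr <- runif(2, g / 3, 2 * g / 3)
  ax <- runif(2, 2, g / 4)
  th <- runif(1, 0, pi)
  m <- matrix(FALSE, g, g)
  for (i in seq_len(g)) for (j in seq_len(g)) {
    dx <- (j - 1 - ctr[2]); dy <- (i - 1 - ctr[1])
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    m[i, j] <- (u / ax[1])^2 + (v / ax[2])^2 <= 1
  }
  m
}

bin_map <- function(mask, px = 33) {
  iosimap:::binary_map_object(mask, px, NULL)
}

ev_map <- function(values, px = 33) {
  iosimap:::evoked_map_object(values, 1L, px)
}
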