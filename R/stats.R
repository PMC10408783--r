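iosi_stat <- function(statistic, p_value, df, method) {
  structure(list(statistic = statistic, p_value = p_value, df = df,
                 method = method),
            class = "iosi_stat")
}

#' @export
print.iosi_stat <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.6g, df = (%s), p = %.4g\n",
              x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p_value))
  invisible(x)
}

#' Compare groups of 2-D map displacements (one-way MANOVA)
#'
#' One-way multivariate ANOVA on `(dx, dy)` displacement vectors using
#' Wilks' lambda with Rao's F approximation (via [stats::manova()]).
#' For two groups this is equivalent to Hotelling's T-squared.
#'
#' @param groups list of two or more matrices/data frames, each
#'   `n_i x 2` of `(dx_um, dy_um)` rows (e.g. from [displacement()]),
#'   one per map type.
#' @return An `iosi_stat` with the Wilks' lambda statistic, approximate-F
#'   degrees of freedom and p-value.
#' @export
compare_displacements <- function(groups) {
  if (length(groups) < 2L)
    stop("compare_displacements: need at least two groups")
  mats <- lapply(groups, function(g) {
    g <- as.matrix(g)
    if (ncol(g) != 2L)
      stop("compare_displacements: each group must be an n x 2 matrix")
    if (nrow(g) < 2L)
      stop("compare_displacements: each group needs >= 2 points")
    g
  })
  y <- do.call(rbind, mats)
  g <- factor(rep(seq_along(mats), vapply(mats, nrow, 0L)))
  if (nrow(y) <= length(mats) + 2L)
    stop("compare_displacements: too few points for 2-D responses")
  fit <- manova(y ~ g)
  st <- tryCatch(summary(fit, test = "Wilks")$stats,
                 error = function(e)
                   stop("compare_displacements: singular pooled covariance (",
                        conditionMessage(e), ")"))
  iosi_stat(statistic = st[1, "Wilks"],
            p_value = st[1, "Pr(>F)"],
            df = c(num_df = st[1, "num Df"], den_df = st[1, "den Df"],
                   approx_F = st[1, "approx F"]),
            method = "One-way MANOVA on 2-D displacements (Wilks' lambda, Rao F)")
}

#' Compare paired map areas (plasticity quantification)
#'
#' Per-map areas for the pre and post lists, group means with SEM, the
#' percent change, and a paired two-tailed t test on the per-pair areas.
#' Because the percent change of the group means and the mean of the
#' per-pair percent changes differ in general, both are reported.
#'
#' @param pre,post equal-length lists of `iosi_binary_map` objects (or
#'   numeric vectors of areas in mm^2), paired by subject.
#' @param paired currently only paired comparisons are supported.
#' @return List with `areas` (data frame of per-pair areas), `mean_pre`,
#'   `mean_post`, `sem_pre`, `sem_post`, `percent_change_of_means`,
#'   `mean_percent_change`, and `test` (an `iosi_stat`).
#' @export
area_change <- function(pre, post, paired = TRUE) {
  if (!paired) stop("area_change: only paired comparison is implemented")
  a_pre <- if (is.numeric(pre)) pre else vapply(pre, map_area, 0)
  a_post <- if (is.numeric(post)) post else vapply(post, map_area, 0)
  if (length(a_pre) != length(a_post))
    stop("area_change: pre and post lists differ in length")
  n <- length(a_pre)
  if (n < 2L) stop("area_change: need at least two pairs")
  d <- a_post - a_pre
  if (all(d == 0)) {
    test <- iosi_stat(0, 1, n - 1, "Paired two-tailed t test")
  } else if (sd(d) == 0) {
    warning("area_change: zero variance of paired differences; ",
            "t statistic degenerate, reporting p = 0")
    test <- iosi_stat(Inf * sign(mean(d)), 0, n - 1,
                      "Paired two-tailed t test (degenerate)")
  } else {
    tt <- t.test(a_post, a_pre, paired = TRUE)
    test <- iosi_stat(unname(tt$statistic), tt$p.value,
                      unname(tt$parameter), "Paired two-tailed t test")
  }
  sem <- function(x) sd(x) / sqrt(length(x))
  list(areas = data.frame(pair = seq_len(n), pre_mm2 = a_pre,
                          post_mm2 = a_post, diff_mm2 = d),
       mean_pre = mean(a_pre), mean_post = mean(a_post),
       sem_pre = sem(a_pre), sem_post = sem(a_post),
       percent_change_of_means = 100 * (mean(a_post) - mean(a_pre)) /
         mean(a_pre),
       mean_percent_change = 100 * mean(d / a_pre),
       test = test)
}
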