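#' Group summary (mean, SD, n)
#'
#' Container for a group reported as mean +/- SD with sample size, the form
#' in which the study's Results tables print every measurement. All the
#' inference functions in this module accept either these summaries or raw
#' replicate vectors; both code paths agree exactly when the replicates
#' realize the summarized moments.
#'
#' @param label Group label.
#' @param mean Group mean.
#' @param sd Group standard deviation (non-negative).
#' @param n Sample size (at least 2).
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(label, mean, sd, n) {
  stopifnot(is.numeric(mean), is.numeric(sd), sd >= 0, n >= 2)
  structure(list(label = as.character(label), mean = mean, sd = sd,
                 n = as.integer(n)), class = "group_summary")
}

#' @rdname group_summary
#' @param x A numeric replicate vector.
#' @export
as_group_summary <- function(x, label = "group") {
  stopifnot(is.numeric(x), length(x) >= 2L)
  group_summary(label, mean(x), sd(x), length(x))
}

.as_summary <- function(g, label = "group") {
  if (inherits(g, "group_summary")) g else as_group_summary(g, label)
}

.stat_result <- function(statistic, value, df, p, method, extra = NULL) {
  structure(c(list(statistic = statistic, value = value, df = df,
                   p.value = p, method = method), extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- paste(format(x$df, digits = 4), collapse = ", ")
  cat(sprintf("%s: %s = %.4g, df = %s, p = %.4g\n", x$method, x$statistic,
              x$value, dfs, x$p.value))
  invisible(x)
}

#' Pearson correlation test
#'
#' Product-moment correlation with the two-sided p value from
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors (length at least 3,
#'   non-constant).
#' @return A `stat_result` with `value = r`, `t`, `df`, `p.value`.
#' @examples
#' v <- rep(c(4, 20, 100, 500), each = 3)
#' ce <- rep(c(85.0, 68.7, 11.3, 1.6), each = 3)
#' pearson_test(v, ce)   # r = -0.772, p = 0.0033
#' @export
pearson_test <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 3L)
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant input: correlation undefined")
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    ((n - 1) * sd(x) * sd(y))
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * pt(-abs(tstat), n - 2)
  .stat_result("r", r, n - 2, p, "Pearson correlation",
               extra = list(t = tstat, n = n))
}

#' Two-sample Student t test from summaries or replicates
#'
#' Pooled-variance Student t by default (`df = n1 + n2 - 2`); Welch's
#' unequal-variance form behind `welch = TRUE`. Operates directly on
#' mean/SD/n summaries, allowing the printed group tables to be tested
#' without the unpublished replicates.
#'
#' @param a,b [group_summary()] objects or numeric replicate vectors.
#' @param welch Use the Welch-Satterthwaite form?
#' @return A `stat_result` with `value = t`, `df`, `p.value`.
#' @examples
#' two_sample_t(group_summary("Mag", 26222, 5102, 6),
#'              group_summary("NonMag", 9620, 1930, 6))  # t = 7.45
#' @export
two_sample_t <- function(a, b, welch = FALSE) {
  a <- .as_summary(a, "a")
  b <- .as_summary(b, "b")
  if (welch) {
    va <- a$sd^2 / a$n
    vb <- b$sd^2 / b$n
    if (va + vb == 0) stop("zero variance in both groups")
    tstat <- (a$mean - b$mean) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
    method <- "Welch two-sample t"
  } else {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    if (sp2 == 0) stop("zero pooled variance")
    tstat <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
    method <- "Pooled two-sample t"
  }
  .stat_result("t", tstat, df, 2 * pt(-abs(tstat), df), method)
}

.groups_to_summaries <- function(groups) {
  if (inherits(groups, "group_summary")) stop("supply a list of groups")
  labs <- names(groups)
  if (is.null(labs)) labs <- paste0("group", seq_along(groups))
  lapply(seq_along(groups), function(i) .as_summary(groups[[i]], labs[i]))
}

#' One-way ANOVA from summaries or replicates
#'
#' Standard between/within decomposition: `F = MSB / MSW` on
#' `(k - 1, N - k)` degrees of freedom, computed from group means, SDs and
#' sizes (or from raw replicates via their summaries, which is exact).
#'
#' @param groups A list of [group_summary()] objects and/or numeric
#'   replicate vectors (at least 2 groups).
#' @return A `stat_result` with `value = F`, `df` (pair), `p.value`, and the
#'   pooled `msw` used by [lsd_posthoc()].
#' @export
one_way_anova <- function(groups) {
  gs <- .groups_to_summaries(groups)
  k <- length(gs)
  stopifnot(k >= 2L)
  ns <- vapply(gs, `[[`, 0, "n")
  means <- vapply(gs, `[[`, 0, "mean")
  sds <- vapply(gs, `[[`, 0, "sd")
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  if (ssw == 0 && ssb == 0) stop("degenerate: no variance at all")
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  if (msw == 0) stop("zero within-group variance")
  Fstat <- msb / msw
  .stat_result("F", Fstat, c(k - 1, N - k),
               pf(Fstat, k - 1, N - k, lower.tail = FALSE),
               "One-way ANOVA", extra = list(msw = msw, ssb = ssb, ssw = ssw))
}

#' Fisher LSD post-hoc pairwise comparisons
#'
#' Least-significant-difference pairwise t tests after a one-way ANOVA,
#' using the pooled within-group mean square on `N - k` degrees of freedom.
#' No multiplicity correction is applied (by design, mirroring LSD usage;
#' interpret with the usual caveat).
#'
#' @inheritParams one_way_anova
#' @return A data frame with one row per pair: `group1`, `group2`, `diff`,
#'   `se`, `t`, `df`, `p.value`.
#' @export
lsd_posthoc <- function(groups) {
  gs <- .groups_to_summaries(groups)
  k <- length(gs)
  stopifnot(k >= 2L)
  aov_res <- one_way_anova(groups)
  msw <- aov_res$msw
  df <- aov_res$df[2]
  pairs <- utils::combn(k, 2)
  out <- apply(pairs, 2, function(idx) {
    a <- gs[[idx[1]]]
    b <- gs[[idx[2]]]
    se <- sqrt(msw * (1 / a$n + 1 / b$n))
    tstat <- (a$mean - b$mean) / se
    data.frame(group1 = a$label, group2 = b$label, diff = a$mean - b$mean,
               se = se, t = tstat, df = df,
               p.value = 2 * pt(-abs(tstat), df))
  })
  do.call(rbind, out)
}

#' Fold ratio of two means
#'
#' Plain ratio of a numerator to a denominator mean, the study's
#' fold-enrichment summary (reported to two decimals).
#'
#' @param numerator,denominator Numeric values; the denominator must be
#'   positive.
#' @return The ratio (full precision; round for reporting).
#' @examples
#' fold_ratio(26222, 9620)  # 2.73
#' @export
fold_ratio <- function(numerator, denominator) {
  stopifnot(is.numeric(numerator), is.numeric(denominator))
  if (any(denominator <= 0)) stop("denominator must be positive")
  numerator / denominator
}

#' Relative MRI signal intensity
#'
#' Signal intensity of the anterior wall divided by that of the
#' interventricular septum, the semiquantitative readout of SPIO-induced
#' hypointensity.
#'
#' @param anterior,septum Signal intensities (septum must be positive).
#' @return The intensity ratio(s).
#' @export
relative_signal_intensity <- function(anterior, septum) {
  stopifnot(is.numeric(anterior), is.numeric(septum))
  if (any(septum <= 0)) stop("septum intensity must be positive")
  anterior / septum
}

#' Cell retention rate
#'
#' Cells detected in the heart divided by cells infused. Values above 1 are
#' physically implausible and flagged with a warning.
#'
#' @param detected Detected cell count(s).
#' @param infused Infused cell count(s) (positive).
#' @return Retention fraction(s).
#' @export
retention_rate <- function(detected, infused) {
  stopifnot(is.numeric(detected), is.numeric(infused))
  if (any(infused <= 0)) stop("infused count must be positive")
  if (any(detected < 0)) stop("detected count must be non-negative")
  rate <- detected / infused
  if (any(rate > 1))
    warning("retention rate > 1 is implausible (more detected than infused)")
  rate
}

#' Capillary density
#'
#' Capillary count per field area; with `aggregate = TRUE` the field-wise
#' densities are averaged (the morphometric protocol averages 10 fields).
#'
#' @param count Capillary counts per field.
#' @param area Field areas in mm^2 (positive).
#' @param aggregate Average across fields?
#' @return Densities per mm^2 (vector, or their mean).
#' @export
capillary_density <- function(count, area, aggregate = FALSE) {
  stopifnot(is.numeric(count), is.numeric(area))
  if (any(area <= 0)) stop("area must be positive")
  if (any(count < 0)) stop("count must be non-negative")
  d <- count / area
  if (aggregate) mean(d) else d
}
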