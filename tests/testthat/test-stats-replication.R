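test_that("pearson_test reproduces exact and velocity-sweep correlations", {
  x <- 1:10
  pe <- pearson_test(x, 2 * x + 1)
  expect_equal(pe$value, 1)
  expect_lt(pe$p.value, 1e-12)
  # 12 replicate points: 4 velocities x triplicate at the summary means
  v <- rep(c(4, 20, 100, 500), each = 3)
  ce <- rep(c(85.0, 68.7, 11.3, 1.6), each = 3)
  ps <- pearson_test(v, ce)
  expect_equal(ps$value, -0.7721, tolerance = 1e-3)
  expect_equal(ps$p.value, 0.00325, tolerance = 1e-2)
  expect_error(pearson_test(rep(1, 5), 1:5), "constant")
})

test_that("pearson_test matches cor.test and a permutation oracle", {
  for (s in 1:4) {
    set.seed(s)
    a <- rnorm(10)
    b <- 0.7 * a + rnorm(10, sd = 0.8)
    mine <- pearson_test(a, b)
    ref <- cor.test(a, b)
    expect_equal(mine$value, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
    # permutation p agrees within Monte-Carlo error on near-normal data
    rp <- replicate(2e4, abs(cor(a, sample(b))))
    perm_p <- mean(rp >= abs(mine$value))
    se <- sqrt(perm_p * (1 - perm_p) / 2e4) + 1e-4
    expect_lt(abs(perm_p - mine$p.value), max(4 * se, 0.005))
  }
})

test_that("pooled t from summaries matches hand computation and raw data", {
  t0 <- two_sample_t(group_summary("a", 5, 1, 6), group_summary("b", 5, 1, 6))
  expect_equal(t0$value, 0)
  expect_equal(t0$p.value, 1)
  # printed fluorescence summaries
  tf <- two_sample_t(group_summary("Mag", 26222, 5102, 6),
                     group_summary("NonMag", 9620, 1930, 6))
  expect_equal(tf$value, 7.455, tolerance = 1e-3)
  expect_equal(tf$df, 10)
  expect_lt(tf$p.value, 0.001)
  # summary path equals the raw-replicate path exactly
  set.seed(2)
  x <- rnorm(8, 10, 2)
  y <- rnorm(6, 8, 3)
  raw <- two_sample_t(x, y)
  summ <- two_sample_t(as_group_summary(x), as_group_summary(y))
  expect_equal(raw$value, summ$value, tolerance = 1e-12)
  # cross-check against t.test, pooled and Welch
  expect_equal(raw$value, unname(t.test(x, y, var.equal = TRUE)$statistic),
               tolerance = 1e-12)
  expect_equal(raw$p.value, t.test(x, y, var.equal = TRUE)$p.value,
               tolerance = 1e-12)
  w <- two_sample_t(x, y, welch = TRUE)
  expect_equal(w$value, unname(t.test(x, y)$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(t.test(x, y)$parameter), tolerance = 1e-9)
  expect_error(two_sample_t(group_summary("a", 1, 0, 3),
                            group_summary("b", 2, 0, 3)), "pooled variance")
})

test_that("one-way ANOVA from summaries matches aov and reduces to t^2", {
  same <- list(group_summary("a", 5, 1, 6), group_summary("b", 5, 1, 6),
               group_summary("c", 5, 1, 6))
  expect_equal(one_way_anova(same)$value, 0)
  set.seed(4)
  g <- list(a = rnorm(6, 10), b = rnorm(7, 11), c = rnorm(5, 12))
  mine <- one_way_anova(g)
  ref <- summary(aov(y ~ grp, data.frame(
    y = unlist(g), grp = rep(names(g), lengths(g)))))[[1]]
  expect_equal(mine$value, ref[["F value"]][1], tolerance = 1e-9)
  expect_equal(mine$p.value, ref[["Pr(>F)"]][1], tolerance = 1e-9)
  # two groups: F = t^2
  two <- one_way_anova(g[1:2])
  tt <- two_sample_t(g$a, g$b)
  expect_equal(two$value, tt$value^2, tolerance = 1e-10)
})

test_that("LSD post hoc flags all printed capillary-density differences", {
  cd <- list(group_summary("PBS", 917, 137, 6),
             group_summary("NonMag", 1200, 85, 6),
             group_summary("Mag", 1558, 166, 6))
  lsd <- lsd_posthoc(cd)
  expect_equal(nrow(lsd), 3)
  expect_true(all(lsd$p.value < 0.05))
  expect_true(all(lsd$df == 15))
  # LSD pairwise t uses the pooled MSE, not the per-pair variances
  aovr <- one_way_anova(cd)
  i <- which(lsd$group1 == "PBS" & lsd$group2 == "NonMag")
  expect_equal(lsd$se[i], sqrt(aovr$msw * (1 / 6 + 1 / 6)), tolerance = 1e-12)
})

test_that("fold ratios reproduce the printed enrichment factors", {
  expect_equal(round(fold_ratio(26222, 9620), 2), 2.73)
  expect_equal(round(fold_ratio(25.8, 8.5), 2), 3.04)
  expect_equal(fold_ratio(7, 7), 1.00)
  expect_error(fold_ratio(1, 0), "positive")
})

test_that("derived metrics: relative SI, retention rate, capillary density", {
  expect_equal(relative_signal_intensity(1.2, 1.2), 1.0)
  expect_equal(relative_signal_intensity(0, 2), 0.0)
  expect_error(relative_signal_intensity(1, 0), "positive")
  si <- two_sample_t(group_summary("Mag", 0.61, 0.06, 6),
                     group_summary("NonMag", 0.88, 0.08, 6))
  expect_lt(si$p.value, 0.01)

  expect_equal(retention_rate(1e5, 1e6), 0.10)
  expect_equal(retention_rate(0, 1e6), 0.0)
  expect_warning(retention_rate(2e6, 1e6), "implausible")
  expect_error(retention_rate(1, 0), "positive")

  expect_equal(capillary_density(10, 0.01), 1000)
  expect_equal(capillary_density(0, 0.5), 0)
  # equal-area fields: field-wise mean equals pooled count / pooled area
  counts <- c(8, 12, 9, 11)
  areas <- rep(0.02, 4)
  expect_equal(capillary_density(counts, areas, aggregate = TRUE),
               sum(counts) / sum(areas))
  expect_error(capillary_density(1, 0), "positive")
})
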