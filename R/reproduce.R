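#' Re-run the study's summary-level results from the packaged fixtures
#'
#' Recomputes the fold enrichments, the Pearson velocity-CE correlation, the
#' pooled-t and ANOVA/LSD significance calls from the packaged summary
#' tables, and (optionally) the Monte-Carlo capture-efficiency velocity
#' sweep, comparing each computed value against its reference. The fixture
#' checks are deterministic and run in seconds; the simulation sweep is the
#' expensive part and is off by default.
#'
#' @param run_simulation Also run the capture simulator over the four bench
#'   velocities and check the monotone CE decline?
#' @param n_cells Cells per velocity for the simulation check.
#' @param seed RNG seed for the stochastic checks.
#' @return A `reproduce_report`: data frame of checks with columns `check`,
#'   `computed`, `reference`, `pass`, plus an `ok` attribute (all passed).
#' @export
reproduce <- function(run_simulation = FALSE, n_cells = 500, seed = 1) {
  checks <- list()
  add <- function(check, computed, reference, pass) {
    checks[[length(checks) + 1]] <<- data.frame(
      check = check, computed = computed, reference = reference, pass = pass)
  }

  fl <- mc_fixture("fluorescence")
  pb <- mc_fixture("prussian_blue")
  ce <- mc_fixture("ce_velocity")
  si <- mc_fixture("relative_signal_intensity")
  cd <- mc_fixture("capillary_density")

  mg <- function(d, g, col) d[[col]][d$group == g]
  f_fold <- fold_ratio(mg(fl, "Mag", "mean_photon_per_s"),
                       mg(fl, "NonMag", "mean_photon_per_s"))
  add("fluorescence fold (Mag/NonMag)", round(f_fold, 2), 2.73,
      round(f_fold, 2) == 2.73)
  p_fold <- fold_ratio(mg(pb, "Mag", "mean_cells_per_field"),
                       mg(pb, "NonMag", "mean_cells_per_field"))
  add("Prussian-blue anterior fold (Mag/NonMag)", round(p_fold, 2), 3.04,
      round(p_fold, 2) == 3.04)

  # Pearson on the 12 replicate points (4 velocities x triplicate), using
  # the summary means replicated per triplicate
  x <- rep(ce$velocity_mm_per_s, ce$n)
  y <- rep(ce$mean_ce_percent, ce$n)
  pe <- pearson_test(x, y)
  add("CE-velocity Pearson r (12 points)", round(pe$value, 3), -0.77,
      abs(pe$value + 0.77) < 0.01)
  add("CE-velocity Pearson p (1 s.f.)", signif(pe$p.value, 1), 0.003,
      signif(pe$p.value, 1) == 0.003)

  gsum <- function(d, g, col, sdcol, ncol = "n")
    group_summary(g, mg(d, g, col), mg(d, g, sdcol), d[[ncol]][d$group == g])
  t_fl <- two_sample_t(gsum(fl, "Mag", "mean_photon_per_s", "sd_photon_per_s"),
                       gsum(fl, "NonMag", "mean_photon_per_s", "sd_photon_per_s"))
  add("fluorescence pooled t: p < 0.001", t_fl$p.value, 0.001,
      t_fl$p.value < 0.001)
  t_pb <- two_sample_t(gsum(pb, "Mag", "mean_cells_per_field", "sd_cells_per_field"),
                       gsum(pb, "NonMag", "mean_cells_per_field", "sd_cells_per_field"))
  add("Prussian-blue pooled t: p < 0.001", t_pb$p.value, 0.001,
      t_pb$p.value < 0.001)
  t_si <- two_sample_t(gsum(si, "Mag", "mean_ratio", "sd_ratio"),
                       gsum(si, "NonMag", "mean_ratio", "sd_ratio"))
  add("relative signal intensity t: p < 0.01", t_si$p.value, 0.01,
      t_si$p.value < 0.01)

  cd_groups <- lapply(cd$group, function(g)
    gsum(cd, g, "mean_per_mm2", "sd_per_mm2"))
  lsd <- lsd_posthoc(cd_groups)
  add("capillary density LSD: all pairwise p < 0.05", max(lsd$p.value), 0.05,
      all(lsd$p.value < 0.05))

  if (run_simulation) {
    curve <- ce_velocity_curve(ce$velocity_mm_per_s * 1e-3, n = n_cells,
                               seed = seed)
    add("simulated CE monotone non-increasing in velocity",
        as.numeric(all(diff(curve$ce_percent) <= 0)), 1,
        all(diff(curve$ce_percent) <= 0))
    ratio <- curve$ce_percent[1] / max(curve$ce_percent[4], 1e-9)
    add("simulated CE(4 mm/s) > 10 x CE(500 mm/s)", ratio, 10, ratio > 10)
  }

  out <- do.call(rbind, checks)
  structure(out, ok = all(out$pass), class = c("reproduce_report",
                                               class(out)))
}

#' @export
print.reproduce_report <- function(x, ...) {
  df <- as.data.frame(x)
  df$computed <- signif(df$computed, 4)
  df$status <- ifelse(df$pass, "PASS", "FAIL")
  print(df[, c("check", "computed", "reference", "status")], row.names = FALSE)
  cat(if (attr(x, "ok")) "\nAll checks passed.\n" else "\nSOME CHECKS FAILED.\n")
  invisible(x)
}
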