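test_that("censoring bounds behave at the limits", {
  reg <- default_registry()
  none <- generate_primo_table(
    generator_config(n_diets = 4, years = 2018L, loq_censor_fraction = 0,
                     seed = 1), reg)$records
  wide_none <- tidyr::pivot_wider(none, names_from = "scenario",
                                  values_from = "percent_adi")
  expect_equal(wide_none$lower, wide_none$middle)
  expect_equal(wide_none$middle, wide_none$upper)

  full <- generate_primo_table(
    generator_config(n_diets = 4, years = 2018L, loq_censor_fraction = 1,
                     seed = 1), reg)$records
  wide_full <- tidyr::pivot_wider(full, names_from = "scenario",
                                  values_from = "percent_adi")
  expect_equal(wide_full$lower, rep(0, nrow(wide_full)))
  expect_equal(wide_full$middle, wide_full$upper / 2)
})

test_that("vanishing inter-diet spread pins %ADI at the dose-to-ADI ratio", {
  reg <- default_registry()
  adi <- stats::setNames(reg$substances$adi_primo, reg$substances$substance)
  doses <- adi[c("cypermethrin", "permethrin")]  # dose = ADI
  rec <- generate_primo_table(
    generator_config(n_diets = 6, years = 2018L, median_doses = doses,
                     sigma = 1e-12, loq_censor_fraction = 0, seed = 4),
    reg)$records
  expect_rel_equal(rec$percent_adi, 100, tol = 1e-6)
})

test_that("generation is deterministic given the seed", {
  cfg <- generator_config(n_diets = 6, years = 2018:2019, n_countries = 2,
                          seed = 99)
  expect_identical(generate_primo_table(cfg), generate_primo_table(cfg))
  expect_identical(generate_hbm_table(cfg), generate_hbm_table(cfg))
  other <- generator_config(n_diets = 6, years = 2018:2019, n_countries = 2,
                            seed = 100)
  expect_false(identical(generate_primo_table(cfg)$records$percent_adi,
                         generate_primo_table(other)$records$percent_adi))
})

test_that("urinary percentile tables are monotone for random configs", {
  set.seed(31)
  for (i in 1:25) {
    cfg <- generator_config(
      n_diets = 4, years = 2018L, n_countries = 2,
      population_gsd = runif(1, 1.01, 4), country_gsd = runif(1, 1, 2),
      measurement_cv = runif(1, 0, 0.3), seed = sample.int(1e6, 1))
    agg <- generate_hbm_table(cfg)$aggregates
    mono <- dplyr::summarise(
      dplyr::group_by(agg, country, age_group, metabolite_id),
      ok = !is.unsorted(concentration), .groups = "drop")
    expect_true(all(mono$ok))
  }
})

test_that("self-consistent generation matches middle-bound dosimetry
          predictions", {
  reg <- default_registry()
  # no censoring, no inter-diet/country spread, generation Fue = analysis Fue
  cfg <- generator_config(n_diets = 4, years = 2018L, sigma = 1e-12,
                          loq_censor_fraction = 0, population_gsd = 1.0001,
                          country_gsd = 1, n_countries = 1, seed = 6)
  prim <- generate_primo_table(cfg, reg)
  hbm <- generate_hbm_table(cfg, reg)
  totals <- predict_totals(prim$records, reg)
  med <- hbm$aggregates[hbm$aggregates$percentile == 50, ]
  joined <- dplyr::inner_join(
    totals[totals$scenario == "middle", ],
    med, by = c("metabolite_id", "age_class" = "age_group"))
  expect_rel_equal(joined$concentration.x, joined$concentration.y,
                   tol = 1e-6)
})

test_that("generation-side excretion override inflates measured levels by
          the assumed ratio", {
  reg <- default_registry()
  cfg_true <- generator_config(n_diets = 4, years = 2018L, n_countries = 1,
                               country_gsd = 1, seed = 12)
  cfg_misspec <- generator_config(n_diets = 4, years = 2018L, n_countries = 1,
                                  country_gsd = 1, seed = 12,
                                  true_fue = c("3PBA" = 0.45))
  base <- generate_hbm_table(cfg_true, reg)$true_medians
  high <- generate_hbm_table(cfg_misspec, reg)$true_medians
  pba <- base$metabolite_id == "3PBA"
  expect_equal(high$true_median[pba] / base$true_median[pba],
               rep(5, sum(pba)))
  expect_equal(high$true_median[!pba], base$true_median[!pba])
})

test_that("allocation on generated data recovers the true contribution
          shares", {
  reg <- default_registry()
  # configuration-level recovery: at sigma = 0.2 the sampling noise of a
  # per-age-class median (SE well under 1 point) leaves +/-2 points as a
  # genuine accuracy band around the configured shares
  cfg <- generator_config(sigma = 0.2, seed = 17)
  prim <- generate_primo_table(cfg, reg)
  levels <- predict_levels(prim$records, reg)
  tab <- summarize_contributions(contribution_percentages(levels, reg))
  mid <- tab[tab$scenario == "middle", ]
  joined <- dplyr::inner_join(mid, prim$truth$shares,
                              by = c("metabolite_id", "substance"))
  expect_true(all(abs(joined$p50 - 100 * joined$share) <= 2))
  expect_true(all(joined$p10 <= joined$p50 & joined$p50 <= joined$p90))
  # shares sum to one per metabolite cell by construction
  sums <- dplyr::summarise(dplyr::group_by(prim$truth$shares, metabolite_id),
                           s = sum(share), .groups = "drop")
  expect_equal(sums$s, rep(1, nrow(sums)))
  # realization-level recovery at the default inter-diet spread: the
  # pipeline reproduces the share structure of the doses actually drawn
  cfg_def <- generator_config(seed = 17)
  prim_def <- generate_primo_table(cfg_def, reg)
  tab_def <- summarize_contributions(contribution_percentages(
    predict_levels(prim_def$records, reg), reg))
  j2 <- dplyr::inner_join(tab_def[tab_def$scenario == "middle", ],
                          prim_def$truth$realized_shares,
                          by = c("metabolite_id", "substance", "age_class"))
  expect_equal(j2$p50, j2$share, tolerance = 1e-9)
})

test_that("censoring-bound ordering survives the full pipeline", {
  res <- run_pipeline(simulate = list(n_diets = 8, years = 2018:2019),
                      seed = 14, monte_carlo = FALSE)
  wide <- tidyr::pivot_wider(res$totals, names_from = "scenario",
                             values_from = "concentration")
  expect_true(all(wide$lower <= wide$middle & wide$middle <= wide$upper))
})
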