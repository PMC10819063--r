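test_that("percent-of-ADI converts to absolute dose", {
  expect_equal(exposure_from_percent_adi(100, 0.005), 0.005)
  expect_equal(exposure_from_percent_adi(0, 0.01), 0)
  expect_equal(exposure_from_percent_adi(23.5, 0.01), 0.00235)
  expect_error(exposure_from_percent_adi(-1, 0.01), ">= 0")
  expect_error(exposure_from_percent_adi(10, 0), "> 0")
})

test_that("forward prediction is consistent with the guidance value", {
  reg <- default_registry()
  u <- urinary_excretion(reg, "adult")
  # dose at the ADI reproduces the guidance value by definition
  expect_equal(predict_metabolite_level(0.01, 0.36, 208.1, 391.2, u),
               derive_hbm_gv(reg, "permethrin", "DCCA", "adult"))
  expect_equal(predict_metabolite_level(0, 0.36, 208.1, 391.2, u), 0)
  # half the revised ADI -> half of 64 ug/L by linearity
  expect_equal(predict_metabolite_level(0.005, 0.36, 208.1, 391.2, u),
               derive_hbm_gv(reg, "permethrin", "DCCA", "adult") / 2)
  expect_lt(abs(predict_metabolite_level(0.005, 0.36, 208.1, 391.2, u) - 32),
            0.05)
})

test_that("guidance-value shortcut equals the two-step dose path", {
  expect_equal(predict_via_hbm_gv(100, 64), 64)
  expect_equal(predict_via_hbm_gv(50, 64), 32)
  set.seed(1)
  reg <- default_registry()
  n <- 1000
  subs <- sample(reg$substances$substance, n, replace = TRUE)
  ages <- sample(c("adult", "child"), n, replace = TRUE)
  pct <- runif(n, 0, 400)
  for (i in seq_len(n)) {
    link <- reg$metabolites[reg$metabolites$substance == subs[i], ][1, ]
    params <- reg$substances[reg$substances$substance == subs[i], ]
    u <- urinary_excretion(reg, ages[i])
    two_step <- predict_metabolite_level(
      exposure_from_percent_adi(pct[i], params$adi_primo),
      link$fue, link$mw_metabolite, params$mw_parent, u)
    gv <- params$adi_primo * link$fue *
      (link$mw_metabolite / params$mw_parent) * 1000 / u
    shortcut <- predict_via_hbm_gv(pct[i], gv)
    expect_equal(shortcut, two_step, tolerance = 1e-9)
  }
})

test_that("diet labels classify into age classes by token", {
  expect_equal(classify_diet(c("DE general", "FR toddler", "UK adult",
                               "ES INFANT", "IT Child diet")),
               c("adult", "child", "adult", "child", "child"))
  expect_error(classify_diet(""), "non-empty")
  expect_equal(classify_diet("NL kids", child_tokens = c("kid")), "child")
})

test_that("totals sum contributing substances per metabolite", {
  reg <- default_registry()
  records <- dcca_fixture_records()
  totals <- predict_totals(records, reg)
  dcca <- totals$concentration[totals$metabolite_id == "DCCA"]
  # hand-built oracle: Sum over substances of %ADI/100 * ADI * Fue * MWr * 1000/U
  expected <- (2 / 100 * 0.01 * 0.36 * (208.1 / 434.3) +
               8 / 100 * 0.005 * 0.36 * (208.1 / 416.3) +
               0.5 / 100 * 0.05 * 0.36 * (208.1 / 391.2)) * 1000 / 0.0299
  expect_equal(dcca, expected)
  # single-substance metabolite: total equals the individual prediction
  f3pba <- totals$concentration[totals$metabolite_id == "F3PBA"]
  expect_equal(f3pba,
               2 / 100 * 0.01 * 0.47 * (232.2 / 434.3) * 1000 / 0.0299)
  expect_error(predict_levels(tibble::tibble(
    diet_id = "D01", diet_label = "x adult", year = 2018L,
    substance = "DDT", scenario = "middle", percent_adi = 1), reg),
    "unknown substance")
})

test_that("predictions are homogeneous and ordered across scenarios", {
  reg <- default_registry()
  cfg <- generator_config(n_diets = 8, years = 2018:2019, seed = 3)
  records <- generate_primo_table(cfg, reg)$records
  totals <- predict_totals(records, reg)
  expect_true(all(totals$concentration >= 0))
  wide <- tidyr::pivot_wider(totals, names_from = "scenario",
                             values_from = "concentration")
  expect_true(all(wide$lower <= wide$middle + 1e-12))
  expect_true(all(wide$middle <= wide$upper + 1e-12))
  # degree-1 homogeneity in percent_adi
  doubled <- records
  doubled$percent_adi <- 2 * doubled$percent_adi
  expect_equal(predict_totals(doubled, reg)$concentration,
               2 * totals$concentration)
})

test_that("predicted quantiles pair with measured percentile curves", {
  reg <- default_registry()
  cfg <- generator_config(n_diets = 12, years = 2018:2020, seed = 5)
  totals <- predict_totals(generate_primo_table(cfg, reg)$records, reg)
  hbm <- hbm_fixture()
  paired <- compare_predicted_measured(totals, hbm)
  expect_true(all(c("measured", "predicted") %in% names(paired)))
  expect_true(all(paired$metabolite_id %in% c("DCCA", "3PBA")))
  # per curve, both columns are nondecreasing in rank
  by_curve <- dplyr::group_by(paired, metabolite_id, scenario)
  mono <- dplyr::summarise(by_curve, ok = !is.unsorted(predicted) &&
                             !is.unsorted(measured), .groups = "drop")
  expect_true(all(mono$ok))
  # predicted values are the type-7 quantiles of the per-diet totals
  sub <- totals[totals$metabolite_id == "DCCA" &
                  totals$scenario == "middle" &
                  totals$age_class == "adult", ]
  got <- paired$predicted[paired$metabolite_id == "DCCA" &
                            paired$scenario == "middle" &
                            paired$percentile == 75][1]
  expect_equal(got, unname(quantile(sub$concentration, 0.75, type = 7)))
  adult_totals <- totals[totals$age_class == "adult", ]
  expect_warning(
    empty <- compare_predicted_measured(
      adult_totals, hbm_fixture(metabolites = "DBCA", age_group = "child")),
    "no shared")
  expect_equal(nrow(empty), 0)
})

test_that("under-assumed excretion fraction depresses predictions below
          measurements", {
  reg <- default_registry()
  cfg <- generator_config(n_diets = 12, years = 2018:2020, seed = 9,
                          loq_censor_fraction = 0,
                          true_fue = c("3PBA" = 0.45),
                          country_gsd = 1, n_countries = 1)
  prim <- generate_primo_table(cfg, reg)
  hbm <- generate_hbm_table(cfg, reg)$aggregates
  totals <- predict_totals(prim$records, reg)
  paired <- compare_predicted_measured(totals, hbm)
  pba <- paired[paired$metabolite_id == "3PBA" & paired$percentile == 50 &
                  paired$scenario == "middle", ]
  # measured medians run ~5x above the middle-bound predictions
  expect_true(all(pba$predicted < pba$measured))
  expect_rel_equal(pba$measured / pba$predicted, 5, tol = 0.35)
})
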