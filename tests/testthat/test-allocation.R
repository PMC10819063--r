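make_levels <- function(concentrations, substances, metabolite = "DCCA",
                        diet = "D01", label = "C01 adult", year = 2018L,
                        scenario = "middle") {
  tibble::tibble(
    diet_id = diet, diet_label = label, year = year, scenario = scenario,
    age_class = classify_diet(label), substance = substances,
    metabolite_id = metabolite, concentration = concentrations
  )
}

test_that("contribution percentages split a cell by relative level", {
  reg <- default_registry()
  eq <- contribution_percentages(
    make_levels(c(3, 3), c("cyfluthrin", "cypermethrin")), reg)
  expect_equal(sort(eq$percent[eq$percent > 0]), c(50, 50))
  tri <- contribution_percentages(
    make_levels(c(1, 2, 7), c("cyfluthrin", "cypermethrin", "permethrin")),
    reg)
  expect_equal(tri$percent[match(c("cyfluthrin", "cypermethrin", "permethrin"),
                                 tri$substance)], c(10, 20, 70))
  expect_error(contribution_percentages(
    make_levels(-1, "cyfluthrin"), reg), ">= 0")
})

test_that("absent substances complete as 0% and CFMP splits over its two
          sources", {
  reg <- default_registry()
  # only cypermethrin observed: the other DCCA sources count as 0%
  solo <- contribution_percentages(make_levels(5, "cypermethrin"), reg)
  expect_setequal(solo$substance,
                  c("cyfluthrin", "cypermethrin", "permethrin"))
  expect_equal(solo$percent[solo$substance == "cypermethrin"], 100)
  expect_equal(sum(solo$percent), 100)
  cfmp <- contribution_percentages(
    make_levels(c(2, 1), c("lambda-cyhalothrin", "bifenthrin"), "CFMP"), reg)
  expect_setequal(cfmp$substance, c("lambda-cyhalothrin", "bifenthrin"))
  # zero-total cells yield missing percents
  zero <- contribution_percentages(make_levels(0, "cypermethrin"), reg)
  expect_true(all(is.na(zero$percent)))
})

test_that("contribution percentages are scale invariant", {
  reg <- default_registry()
  base <- make_levels(c(1, 2, 7),
                      c("cyfluthrin", "cypermethrin", "permethrin"))
  scaled <- base
  scaled$concentration <- base$concentration * 37.5
  expect_equal(contribution_percentages(scaled, reg)$percent,
               contribution_percentages(base, reg)$percent)
})

test_that("percentile summaries follow the inclusive interpolation
          convention", {
  reg <- default_registry()
  levels <- dplyr::bind_rows(lapply(1:5, function(d) {
    make_levels(c(10 * d, 100 - 10 * d),
                c("lambda-cyhalothrin", "bifenthrin"), "CFMP",
                diet = sprintf("D%02d", d), label = sprintf("C%02d adult", d))
  }))
  contrib <- contribution_percentages(levels, reg)
  tab <- summarize_contributions(contrib)
  chal <- tab[tab$substance == "lambda-cyhalothrin", ]
  # shares are 10..50 across diets; median of {10,20,30,40,50} is 30
  expect_equal(chal$p50, 30)
  # constant shares collapse all percentiles
  const <- contribution_percentages(
    make_levels(c(6, 4), c("lambda-cyhalothrin", "bifenthrin"), "CFMP"), reg)
  ctab <- summarize_contributions(const)
  expect_equal(ctab$p10, ctab$p90)
})

test_that("two-contributor percentiles are exactly complementary", {
  reg <- default_registry()
  set.seed(8)
  levels <- dplyr::bind_rows(lapply(1:17, function(d) {
    make_levels(runif(2, 0.1, 5),
                c("lambda-cyhalothrin", "bifenthrin"), "CFMP",
                diet = sprintf("D%02d", d), label = sprintf("C%02d adult", d))
  }))
  tab <- summarize_contributions(contribution_percentages(levels, reg))
  a <- tab[tab$substance == "lambda-cyhalothrin", ]
  b <- tab[tab$substance == "bifenthrin", ]
  expect_equal(a$p10 + b$p90, 100)
  expect_equal(a$p50 + b$p50, 100)
  expect_equal(a$p90 + b$p10, 100)
})

test_that("attribution partitions a measured level", {
  expect_equal(attribute_measured_level(10, 100), 10)
  expect_equal(attribute_measured_level(10, 25), 2.5)
  expect_error(attribute_measured_level(10, 120), "\\[0, 100\\]")
  pct <- c(12.5, 55, 32.5)
  expect_equal(sum(attribute_measured_level(8, pct)), 8)
})

test_that("molar back-calculation has correct units and Fue scaling", {
  expect_equal(molar_parent_equivalent(208.1, 100, 208.1, 1), 1)
  expect_equal(molar_parent_equivalent(10, 50, 208.1, 0.18),
               2 * molar_parent_equivalent(10, 50, 208.1, 0.36))
  expect_error(molar_parent_equivalent(10, 50, 208.1, 0), "fue must be > 0")
})

test_that("cross-metabolite regression matches the normal equations", {
  d <- tibble::tibble(pba_based = c(1, 2, 3, 5, 8),
                      selective_based = c(0.3, 0.5, 0.55, 1.2, 1.5))
  fit <- cross_metabolite_regression(d)
  # independent oracle: least squares via the normal equations
  X <- cbind(1, d$pba_based)
  beta <- solve(t(X) %*% X, t(X) %*% d$selective_based)
  expect_equal(fit$intercept, beta[1])
  expect_equal(fit$slope, beta[2])
  res <- d$selective_based - X %*% beta
  expect_equal(fit$r_squared,
               1 - sum(res^2) / sum((d$selective_based -
                                       mean(d$selective_based))^2))
  exact <- cross_metabolite_regression(
    tibble::tibble(pba_based = 1:4, selective_based = 1:4))
  expect_equal(exact$slope, 1)
  expect_equal(exact$r_squared, 1)
  expect_error(cross_metabolite_regression(
    tibble::tibble(pba_based = c(2, 2, 2), selective_based = 1:3)),
    "zero variance")
  flipped <- cross_metabolite_regression(d, response = "pba")
  expect_equal(flipped$slope,
               cross_metabolite_regression(
                 tibble::tibble(pba_based = d$selective_based,
                                selective_based = d$pba_based))$slope)
})

test_that("noise-free misspecified excretion fraction gives the exact
          closed-form ratio", {
  reg <- default_registry()
  # sigma ~ 0 removes inter-diet spread: shares sit exactly at the weight
  # ratios and the back-calculated ratio collapses to Fue_true / Fue_assumed
  cfg <- generator_config(n_diets = 12, years = 2018L, seed = 2,
                          sigma = 1e-12, true_fue = c("3PBA" = 0.45),
                          country_gsd = 1, measurement_cv = 0,
                          n_countries = 2)
  prim <- generate_primo_table(cfg, reg)
  hbm <- generate_hbm_table(cfg, reg)$aggregates
  levels <- predict_levels(prim$records, reg)
  ctab <- summarize_contributions(contribution_percentages(levels, reg))
  est <- cross_metabolite_estimates(hbm, ctab, reg,
                                    substances = "cypermethrin")
  expect_rel_equal(est$pba_based / est$selective_based, 5, tol = 1e-6)
})
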