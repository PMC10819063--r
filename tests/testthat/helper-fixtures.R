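# Shared fixtures, built in code.

# A three-substance, one-diet exposure table: the DCCA contributors at one
# middle-bound cell plus a lower/upper pair for ordering checks.
dcca_fixture_records <- function() {
  tibble::tibble(
    diet_id = "D01", diet_label = "C01 adult", year = 2018L,
    substance = c("cyfluthrin", "cypermethrin", "permethrin"),
    scenario = "middle",
    percent_adi = c(2, 8, 0.5)
  )
}

# Minimal measured-aggregate table covering one adult group.
hbm_fixture <- function(metabolites = c("DCCA", "3PBA"),
                        ranks = c(5, 25, 50, 75, 95), median = 4,
                        gsd = 2, country = "XX", age_group = "adult") {
  tidyr::crossing(country = country, age_group = age_group,
                  metabolite_id = metabolites, percentile = ranks) |>
    dplyr::mutate(concentration = median * gsd^stats::qnorm(percentile / 100),
                  unit = "ug/L")
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol * abs(expected)),
              label = sprintf("max rel. dev. %.3g within %.3g",
                              max(abs(actual - expected) / abs(expected)),
                              tol))
}
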