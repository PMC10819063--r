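#' Configuration for the synthetic study generator
#'
#' Defines the conditions under which synthetic dietary-risk tables and
#' aggregated urinary percentile tables are generated. Defaults emulate the
#' structure of the real study inputs: 36 national/generic diets over the
#' years 2016-2020, exposures well below the ADI with cypermethrin the
#' leading contributor to DCCA and lambda-cyhalothrin to CFMP, heavy
#' below-LOQ censoring, and lognormal inter-diet, inter-country and
#' inter-individual variability.
#'
#' @param n_diets Number of diets (default 36); every fourth diet label
#'   carries a children's token (toddler/child/infant).
#' @param years Calendar years covered (default 2016:2020).
#' @param median_doses Named vector of true median dietary doses, mg/kg
#'   bw/day. Defaults are calibrated to sub-ADI exposures reproducing the
#'   reported contribution structure of the shared metabolites.
#' @param sigma Inter-diet lognormal standard deviation (log scale) of the
#'   true doses; scalar or named per substance (default 0.5).
#' @param loq_censor_fraction Fraction of the underlying residue mass below
#'   the limit of quantification, in \[0, 1\]; scalar or named per substance
#'   (default 0.5). Drives the spread between the lower (censored mass = 0),
#'   middle (= LOQ/2) and upper (= LOQ) bound scenarios.
#' @param true_fue Named vector of generation-side molar excretion fractions
#'   per metabolite id, overriding the analysis (registry) values; used to
#'   emulate excretion-fraction misspecification (e.g. `c("3PBA" = 0.45)`
#'   against the conservative analysis value 0.09).
#' @param population_gsd Geometric standard deviation of inter-individual
#'   urinary levels within a population group (default 2.0, a typical spread
#'   for spot-urine biomarkers).
#' @param country_gsd Geometric standard deviation of the country-level
#'   exposure multiplier (default 1.5): synthetic countries are samples of
#'   the same generating process at different overall dietary levels.
#' @param measurement_cv Coefficient of variation of multiplicative
#'   measurement/aggregation noise on each reported group median (default 0).
#' @param percentiles Percentile grid reported in the urinary tables.
#' @param n_countries Number of synthetic countries (default 5).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A validated `pyr_generator_config` list.
#' @export
generator_config <- function(n_diets = 36,
                             years = 2016:2020,
                             median_doses = c(
                               "cyfluthrin"         = 8.0e-5,
                               "cypermethrin"       = 4.0e-4,
                               "permethrin"         = 1.0e-4,
                               "deltamethrin"       = 3.2e-4,
                               "lambda-cyhalothrin" = 1.2e-4,
                               "bifenthrin"         = 5.6e-5),
                             sigma = 0.5,
                             loq_censor_fraction = 0.5,
                             true_fue = NULL,
                             population_gsd = 2.0,
                             country_gsd = 1.5,
                             measurement_cv = 0,
                             percentiles = c(5, 10, 25, 50, 75, 90, 95),
                             n_countries = 5,
                             seed = 1L) {
  cfg <- list(n_diets = as.integer(n_diets), years = as.integer(years),
              median_doses = median_doses, sigma = sigma,
              loq_censor_fraction = loq_censor_fraction, true_fue = true_fue,
              population_gsd = population_gsd, country_gsd = country_gsd,
              measurement_cv = measurement_cv, percentiles = percentiles,
              n_countries = as.integer(n_countries), seed = as.integer(seed))
  if (cfg$n_diets < 1) stop("n_diets must be >= 1", call. = FALSE)
  if (any(cfg$median_doses < 0)) stop("doses must be >= 0", call. = FALSE)
  if (is.null(names(cfg$median_doses))) {
    stop("median_doses must be named by substance", call. = FALSE)
  }
  if (any(cfg$loq_censor_fraction < 0 | cfg$loq_censor_fraction > 1)) {
    stop("loq_censor_fraction must be in [0, 1]", call. = FALSE)
  }
  if (any(cfg$sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  if (cfg$population_gsd < 1 || cfg$country_gsd < 1) {
    stop("geometric standard deviations must be >= 1", call. = FALSE)
  }
  if (cfg$measurement_cv < 0) stop("measurement_cv must be >= 0", call. = FALSE)
  if (any(cfg$percentiles <= 0 | cfg$percentiles >= 100)) {
    stop("percentiles must be inside (0, 100)", call. = FALSE)
  }
  if (!is.null(cfg$true_fue) &&
      (is.null(names(cfg$true_fue)) || any(cfg$true_fue <= 0))) {
    stop("true_fue must be a named (by metabolite) vector of positive values",
         call. = FALSE)
  }
  structure(cfg, class = "pyr_generator_config")
}

.per_substance <- function(x, substances) {
  if (length(x) == 1 && is.null(names(x))) {
    return(stats::setNames(rep(x, length(substances)), substances))
  }
  out <- x[substances]
  if (anyNA(out)) stop("missing per-substance value(s)", call. = FALSE)
  out
}

.diet_labels <- function(n_diets) {
  child_types <- c("toddler", "child", "infant")
  adult_types <- c("general", "adult")
  vapply(seq_len(n_diets), function(i) {
    cc <- sprintf("C%02d", i)
    if (i %% 4 == 0) {
      paste(cc, child_types[(i %/% 4 - 1) %% 3 + 1])
    } else {
      paste(cc, adult_types[i %% 2 + 1])
    }
  }, character(1))
}

#' Generate a synthetic diet-level dietary risk table
#'
#' Draws a true dietary dose per (diet, year, substance) from a lognormal
#' with the configured median and inter-diet sigma, splits the dose into a
#' quantified and a below-LOQ mass fraction, and reports the three censoring
#' bounds as percent of the substance's `primo`-vintage ADI:
#' lower = quantified mass only, middle = quantified + half the censored
#' mass, upper = the full dose. Lower <= middle <= upper by construction,
#' with equality when the censored fraction is zero.
#'
#' @param config A [generator_config()].
#' @param reg A `pyr_registry` providing ADIs, molecular weights and
#'   analysis-side excretion fractions.
#' @return List with `records` (tibble: `diet_id`, `diet_label`, `year`,
#'   `substance`, `scenario`, `percent_adi`) and `truth` (list with `doses`,
#'   the per-(diet, year, substance) true doses; `shares`, the per-
#'   (metabolite, substance) contribution shares implied by the median doses
#'   under the analysis excretion fractions, summing to 1 per metabolite;
#'   and `realized_shares`, the median per-(metabolite, substance, age class)
#'   contribution share of the doses actually drawn, the reference for
#'   end-to-end recovery checks).
#' @export
generate_primo_table <- function(config, reg = default_registry()) {
  stopifnot(inherits(config, "pyr_generator_config"))
  substances <- names(config$median_doses)
  unknown <- setdiff(substances, reg$substances$substance)
  if (length(unknown) > 0) {
    stop("median_doses name(s) not in registry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sigma <- .per_substance(config$sigma, substances)
  censor <- .per_substance(config$loq_censor_fraction, substances)
  set.seed(config$seed)

  grid <- tidyr::crossing(
    tibble::tibble(diet_id = sprintf("D%02d", seq_len(config$n_diets)),
                   diet_label = .diet_labels(config$n_diets)),
    year = config$years,
    substance = substances
  )
  grid$dose <- unname(config$median_doses[grid$substance] *
                        exp(stats::rnorm(nrow(grid)) * sigma[grid$substance]))
  f <- unname(censor[grid$substance])
  adi <- stats::setNames(reg$substances$adi_primo, reg$substances$substance)
  records <- tidyr::pivot_longer(
    dplyr::mutate(grid,
                  lower = .data$dose * (1 - f),
                  middle = .data$dose * (1 - f / 2),
                  upper = .data$dose),
    cols = c("lower", "middle", "upper"),
    names_to = "scenario", values_to = "scenario_dose"
  )
  records$percent_adi <- unname(records$scenario_dose /
                                  adi[records$substance] * 100)
  records <- dplyr::select(records, "diet_id", "diet_label", "year",
                           "substance", "scenario", "percent_adi")

  links <- dplyr::left_join(reg$metabolites, reg$substances, by = "substance")
  links <- links[links$substance %in% substances, ]
  links$weight <- unname(config$median_doses[links$substance]) * links$fue *
    links$mw_metabolite / links$mw_parent
  shares <- dplyr::mutate(
    dplyr::group_by(links, .data$metabolite_id),
    share = .data$weight / sum(.data$weight)
  )
  shares <- dplyr::select(dplyr::ungroup(shares), "metabolite_id",
                          "substance", "share")

  # realization-level shares: the metabolite-share structure of the doses
  # actually drawn, the reference for end-to-end recovery checks
  realized <- dplyr::inner_join(
    dplyr::select(links, "substance", "metabolite_id", "fue",
                  "mw_metabolite", "mw_parent"),
    grid, by = "substance", relationship = "many-to-many")
  realized$w <- realized$dose * realized$fue * realized$mw_metabolite /
    realized$mw_parent
  realized <- dplyr::mutate(
    dplyr::group_by(realized, .data$metabolite_id, .data$diet_id, .data$year),
    cell_share = 100 * .data$w / sum(.data$w))
  realized <- dplyr::ungroup(realized)
  realized$age_class <- classify_diet(realized$diet_label)
  realized_shares <- dplyr::summarise(
    dplyr::group_by(realized, .data$metabolite_id, .data$substance,
                    .data$age_class),
    share = stats::quantile(.data$cell_share, 0.5, type = 7, names = FALSE),
    .groups = "drop")

  list(records = records,
       truth = list(doses = dplyr::select(grid, "diet_id", "diet_label",
                                          "year", "substance", "dose"),
                    shares = shares,
                    realized_shares = realized_shares))
}

#' Generate synthetic aggregated urinary percentile tables
#'
#' Emulates aggregated human-biomonitoring exports: for each synthetic
#' country and age group, the population median of each metabolite is the
#' steady-state urinary level implied by the configured median dietary doses
#' under the *generation-side* excretion fractions (the registry values,
#' overridden by `true_fue` where given), scaled by a country-level exposure
#' multiplier and optional measurement noise. The reported percentile grid
#' follows a lognormal with the configured inter-individual geometric
#' standard deviation around that median, so percentile tables are monotone
#' by construction.
#'
#' The generator stream continues from [generate_primo_table()]'s seed
#' space: the seed used is `config$seed + 1`, so the two tables are
#' independently reproducible.
#'
#' @inheritParams generate_primo_table
#' @return List with `aggregates` (tibble: `country`, `age_group`,
#'   `metabolite_id`, `percentile`, `concentration` in µg/L, `unit`) and
#'   `true_medians` (the noise-free group medians, µg/L, including the
#'   country multiplier).
#' @export
generate_hbm_table <- function(config, reg = default_registry()) {
  stopifnot(inherits(config, "pyr_generator_config"))
  substances <- names(config$median_doses)
  links <- dplyr::left_join(reg$metabolites, reg$substances, by = "substance")
  links <- links[links$substance %in% substances, ]
  fue_gen <- links$fue
  if (!is.null(config$true_fue)) {
    ids <- canonical_metabolite(names(config$true_fue))
    override <- stats::setNames(as.numeric(config$true_fue), ids)
    hit <- links$metabolite_id %in% ids
    fue_gen[hit] <- override[links$metabolite_id[hit]]
  }
  links$level_per_u <- unname(config$median_doses[links$substance]) *
    fue_gen * links$mw_metabolite / links$mw_parent * 1000
  base <- dplyr::summarise(
    dplyr::group_by(links, .data$metabolite_id),
    level_per_u = sum(.data$level_per_u), .groups = "drop"
  )

  set.seed(config$seed + 1L)
  groups <- tidyr::crossing(
    country = sprintf("SY%02d", seq_len(config$n_countries)),
    age_group = c("adult", "child")
  )
  groups$multiplier <- exp(stats::rnorm(nrow(groups)) *
                             log(config$country_gsd))
  cells <- tidyr::crossing(groups, base)
  u <- stats::setNames(reg$population$urinary_excretion,
                       reg$population$age_class)
  cells$true_median <- cells$level_per_u / unname(u[cells$age_group]) *
    cells$multiplier
  noise <- if (config$measurement_cv > 0) {
    sdlog <- sqrt(log(1 + config$measurement_cv^2))
    exp(stats::rnorm(nrow(cells)) * sdlog)
  } else {
    rep(1, nrow(cells))
  }
  cells$reported_median <- cells$true_median * noise

  aggregates <- tidyr::crossing(
    dplyr::select(cells, "country", "age_group", "metabolite_id",
                  "reported_median"),
    percentile = config$percentiles
  )
  aggregates$concentration <- aggregates$reported_median *
    config$population_gsd^stats::qnorm(aggregates$percentile / 100)
  aggregates <- dplyr::arrange(
    dplyr::transmute(aggregates,
                     country = .data$country, age_group = .data$age_group,
                     metabolite_id = .data$metabolite_id,
                     percentile = .data$percentile,
                     concentration = .data$concentration, unit = "ug/L"),
    .data$country, .data$age_group, .data$metabolite_id, .data$percentile
  )
  list(aggregates = aggregates,
       true_medians = dplyr::select(cells, "country", "age_group",
                                    "metabolite_id", "true_median"))
}
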