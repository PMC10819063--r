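#' Convert a dietary risk estimate (% of ADI) to a daily dose
#'
#' Dietary risk model outputs report chronic exposure per diet as a percentage
#' of the acceptable daily intake. The absolute dose is recovered as
#' `percent_adi * adi / 100`.
#'
#' @param percent_adi Exposure as percent of the ADI (>= 0, vectorised).
#' @param adi Acceptable daily intake, mg/kg bw/day (> 0).
#' @return Dose in mg/kg bw/day.
#' @examples
#' exposure_from_percent_adi(100, 0.005)  # exposure at the ADI
#' @export
exposure_from_percent_adi <- function(percent_adi, adi) {
  if (any(!is.finite(percent_adi)) || any(percent_adi < 0)) {
    stop("percent_adi must be finite and >= 0", call. = FALSE)
  }
  if (any(adi <= 0)) stop("adi must be > 0", call. = FALSE)
  percent_adi * adi / 100
}

#' Predict a urinary metabolite concentration from a parent dose
#'
#' Steady-state mass-balance prediction: a daily parent dose (mg/kg bw/day)
#' excreted in urine with molar fraction Fue, converted from parent to
#' metabolite mass by the molecular weight ratio, and diluted in the
#' body-weight-adjusted daily urine volume U (L/kg bw/day):
#' \deqn{C = dose \times Fue \times \frac{MW_{met}}{MW_{parent}} \times
#'   \frac{1000}{U} \quad [\mu g/L]}
#'
#' @param dose Parent dietary dose, mg/kg bw/day (>= 0, vectorised).
#' @param fue Molar urinary excretion fraction in (0, 1].
#' @param mw_metabolite,mw_parent Molecular weights, g/mol.
#' @param u Body-weight-adjusted daily urinary excretion, L/kg bw/day.
#' @return Concentration in µg metabolite / L urine.
#' @examples
#' # permethrin -> DCCA, adult, dose at half the revised ADI: ~32 ug/L
#' predict_metabolite_level(0.005, 0.36, 208.1, 391.2, 0.0299)
#' @export
predict_metabolite_level <- function(dose, fue, mw_metabolite, mw_parent, u) {
  if (any(dose < 0)) stop("dose must be >= 0", call. = FALSE)
  if (any(fue <= 0 | fue > 1)) stop("fue must be in (0, 1]", call. = FALSE)
  if (any(mw_metabolite <= 0) || any(mw_parent <= 0)) {
    stop("molecular weights must be > 0", call. = FALSE)
  }
  if (any(u <= 0)) stop("u must be > 0", call. = FALSE)
  dose * fue * (mw_metabolite / mw_parent) * 1000 / u
}

#' Predict a urinary level directly from %ADI via a guidance value
#'
#' Because the guidance value is the urinary level expected at exposure equal
#' to the ADI, a dietary risk estimate expressed as %ADI maps linearly onto
#' the urinary scale: `concentration = hbm_gv * percent_adi / 100`. When the
#' same ADI and urinary excretion underlie both paths, this is algebraically
#' identical to composing [exposure_from_percent_adi()] with
#' [predict_metabolite_level()].
#'
#' @inheritParams exposure_from_percent_adi
#' @param hbm_gv Guidance value, µg/L (>= 0).
#' @return Concentration in µg/L.
#' @export
predict_via_hbm_gv <- function(percent_adi, hbm_gv) {
  if (any(!is.finite(percent_adi)) || any(percent_adi < 0)) {
    stop("percent_adi must be finite and >= 0", call. = FALSE)
  }
  if (any(hbm_gv < 0)) stop("hbm_gv must be >= 0", call. = FALSE)
  hbm_gv * percent_adi / 100
}

#' Classify a diet label into an age class
#'
#' Diet labels in dietary risk model outputs are free text. Labels containing
#' an infant/toddler/child token (case-insensitive substring match) are
#' classified as `"child"`; every other label, including those marked
#' "general", as `"adult"`.
#'
#' @param diet_label Character vector of diet labels.
#' @param child_tokens Tokens identifying children's diets; user-extensible.
#' @return Character vector, `"adult"` or `"child"`.
#' @examples
#' classify_diet(c("DE general", "FR toddler", "UK adult"))
#' @export
classify_diet <- function(diet_label,
                          child_tokens = c("infant", "toddler", "child")) {
  if (any(!nzchar(diet_label))) stop("diet_label must be non-empty", call. = FALSE)
  pattern <- paste(child_tokens, collapse = "|")
  ifelse(grepl(pattern, diet_label, ignore.case = TRUE), "child", "adult")
}

#' Per-substance predicted urinary levels for a table of exposure records
#'
#' Expands each (diet, year, substance, scenario) record into one row per
#' metabolite link of the substance and predicts the urinary concentration
#' from the %ADI value using the registry's `primo`-vintage ADI (the vintage
#' the dietary risk estimates were computed against) and the age class
#' implied by the diet label.
#'
#' @param records Tibble of exposure records with columns `diet_id`,
#'   `diet_label`, `year`, `substance`, `scenario`, `percent_adi`.
#' @param reg A `pyr_registry`.
#' @param skip_unknown Drop records whose substance is not in the registry
#'   (default `FALSE`: unknown substances abort with a listing).
#' @return Tibble with one row per (record, metabolite link):
#'   `diet_id`, `diet_label`, `year`, `scenario`, `age_class`, `substance`,
#'   `metabolite_id`, `concentration` (µg/L).
#' @export
predict_levels <- function(records, reg, skip_unknown = FALSE) {
  required <- c("diet_id", "diet_label", "year", "substance", "scenario",
                "percent_adi")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("records is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(records$substance), reg$substances$substance)
  if (length(unknown) > 0) {
    if (!skip_unknown) {
      stop("unknown substance(s) in records: ", paste(unknown, collapse = ", "),
           "; rerun with skip_unknown = TRUE to drop them", call. = FALSE)
    }
    records <- records[!records$substance %in% unknown, ]
  }
  records$age_class <- classify_diet(records$diet_label)
  expanded <- dplyr::inner_join(records, reg$metabolites, by = "substance",
                                relationship = "many-to-many")
  expanded <- dplyr::left_join(expanded, reg$substances, by = "substance")
  expanded <- dplyr::left_join(expanded, reg$population, by = "age_class")
  dose <- exposure_from_percent_adi(expanded$percent_adi, expanded$adi_primo)
  expanded$concentration <- predict_metabolite_level(
    dose, expanded$fue, expanded$mw_metabolite, expanded$mw_parent,
    expanded$urinary_excretion
  )
  dplyr::select(expanded, "diet_id", "diet_label", "year", "scenario",
                "age_class", "substance", "metabolite_id", "concentration")
}

#' Total predicted metabolite levels across contributing substances
#'
#' Sums the per-substance predictions of [predict_levels()] over all
#' substances contributing to the same metabolite, per (diet, year, scenario,
#' age class, metabolite).
#'
#' @inheritParams predict_levels
#' @return Tibble with `diet_id`, `diet_label`, `year`, `scenario`,
#'   `age_class`, `metabolite_id`, `concentration` (µg/L, summed).
#' @export
predict_totals <- function(records, reg, skip_unknown = FALSE) {
  levels <- predict_levels(records, reg, skip_unknown = skip_unknown)
  dplyr::summarise(
    dplyr::group_by(levels, .data$diet_id, .data$diet_label, .data$year,
                    .data$scenario, .data$age_class, .data$metabolite_id),
    concentration = sum(.data$concentration),
    .groups = "drop"
  )
}

#' Pair predicted per-diet distributions with measured percentile curves
#'
#' For each metabolite and age class shared between the predicted totals and
#' a table of measured urinary percentile aggregates, evaluates the quantiles
#' of the predicted per-diet totals (pooled over diets and years, per
#' censoring scenario) at the measured percentile ranks, yielding a paired
#' table of measured vs predicted concentrations. No statistical test is
#' attached; the table supports distribution-overlay comparison.
#'
#' @param totals Output of [predict_totals()].
#' @param hbm Tibble of measured aggregates with columns `country`,
#'   `age_group`, `metabolite_id`, `percentile`, `concentration`
#'   (see [read_hbm_aggregates()]).
#' @param percentile_type Quantile convention passed to [stats::quantile()]
#'   (default 7, inclusive linear interpolation).
#' @return Tibble with `metabolite_id`, `age_class`, `country`, `scenario`,
#'   `percentile`, `measured`, `predicted` (both µg/L). Empty (with a
#'   warning) if the two inputs share no metabolite/age class.
#' @export
compare_predicted_measured <- function(totals, hbm, percentile_type = 7) {
  hbm <- dplyr::rename(hbm, age_class = "age_group")
  keys <- dplyr::distinct(totals, .data$metabolite_id, .data$age_class)
  shared <- dplyr::inner_join(
    dplyr::distinct(hbm, .data$metabolite_id, .data$age_class), keys,
    by = c("metabolite_id", "age_class")
  )
  if (nrow(shared) == 0) {
    warning("no shared (metabolite, age class) between predictions and ",
            "measurements; empty comparison", call. = FALSE)
    return(tibble::tibble(metabolite_id = character(), age_class = character(),
                          country = character(), scenario = character(),
                          percentile = numeric(), measured = numeric(),
                          predicted = numeric()))
  }
  pred_q <- dplyr::reframe(
    dplyr::group_by(totals, .data$metabolite_id, .data$age_class,
                    .data$scenario),
    percentile = sort(unique(hbm$percentile)),
    predicted = stats::quantile(.data$concentration,
                                probs = sort(unique(hbm$percentile)) / 100,
                                type = percentile_type, names = FALSE)
  )
  out <- dplyr::inner_join(
    dplyr::select(hbm, "country", "age_class", "metabolite_id", "percentile",
                  measured = "concentration"),
    pred_q,
    by = c("metabolite_id", "age_class", "percentile"),
    relationship = "many-to-many"
  )
  dplyr::arrange(
    dplyr::select(out, "metabolite_id", "age_class", "country", "scenario",
                  "percentile", "measured", "predicted"),
    .data$metabolite_id, .data$age_class, .data$country, .data$scenario,
    .data$percentile
  )
}
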