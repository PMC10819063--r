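#' Hazard quotient of an attributed urinary level
#'
#' Ratio of the urinary concentration attributed to a substance to that
#' substance's guidance value for the same metabolite and age class. Values
#' below 1 indicate no exceedance of the reference.
#'
#' @param attributed_level Attributed concentration, µg/L (>= 0, vectorised).
#' @param hbm_gv Guidance value, µg/L (> 0).
#' @return Dimensionless hazard quotient.
#' @export
hazard_quotient <- function(attributed_level, hbm_gv) {
  if (any(hbm_gv <= 0)) {
    stop("hbm_gv must be > 0 (check the registry/ADI configuration)",
         call. = FALSE)
  }
  if (any(attributed_level < 0)) {
    stop("attributed_level must be >= 0", call. = FALSE)
  }
  attributed_level / hbm_gv
}

#' Cumulative hazard quotient per shared metabolite
#'
#' Sums the per-substance hazard quotients of all substances contributing to
#' the same metabolite within one population cell (country, age group,
#' percentile rank).
#'
#' Given a numeric vector, returns its plain sum (0 with a warning when
#' empty). Given a tibble of per-substance results (as produced by
#' [assess_risk()]), returns one row per (country, age_group, percentile,
#' metabolite) with the summed `cumulative_hq`.
#'
#' @param hq Numeric vector of hazard quotients from one cell, or a tibble
#'   with columns `country`, `age_group`, `percentile`, `metabolite_id`,
#'   `hq`.
#' @return Numeric scalar or summary tibble.
#' @export
cumulative_hq <- function(hq) {
  if (is.numeric(hq)) {
    if (length(hq) == 0) {
      warning("no hazard quotients to sum; returning 0", call. = FALSE)
      return(0)
    }
    if (any(hq < 0)) stop("hazard quotients must be >= 0", call. = FALSE)
    return(sum(hq))
  }
  dplyr::summarise(
    dplyr::group_by(hq, .data$country, .data$age_group, .data$percentile,
                    .data$metabolite_id),
    cumulative_hq = sum(.data$hq),
    n_substances = dplyr::n(),
    .groups = "drop"
  )
}

#' Map each substance to its most selective measured metabolite
#'
#' For combined (across-substance) totals, each substance is represented
#' once, through its most selective metabolite: the substance-unique
#' metabolites where available (DBCA for deltamethrin, F3PBA for cyfluthrin),
#' otherwise the most specific shared acid metabolite (DCCA for cypermethrin
#' and permethrin, CFMP for lambda-cyhalothrin and bifenthrin) with
#' allocation percentages applied. The generic metabolite 3-PBA is never
#' selected: its very conservative excretion fraction makes 3-PBA-derived
#' hazard quotients unrealistically high.
#'
#' @return Named character vector, substance -> metabolite id.
#' @export
selective_metabolite_map <- function() {
  c("deltamethrin"       = "DBCA",
    "cyfluthrin"         = "F3PBA",
    "cypermethrin"       = "DCCA",
    "permethrin"         = "DCCA",
    "lambda-cyhalothrin" = "CFMP",
    "bifenthrin"         = "CFMP")
}

#' Combined pyrethroid risk across substances
#'
#' Sums, per population cell, the hazard quotients obtained from each
#' substance's most selective metabolite (see [selective_metabolite_map()]),
#' counting every substance at most once. Substances with no hazard quotient
#' available for their selective metabolite are omitted with a message.
#'
#' @param hq_results Per-substance results from [assess_risk()] (columns
#'   `country`, `age_group`, `percentile`, `metabolite_id`, `substance`,
#'   `hq`).
#' @param map Substance -> metabolite selection map.
#' @return Tibble with one row per (country, age_group, percentile):
#'   `total_hq`, `n_substances`, and a `components` list-column holding the
#'   per-substance rows that entered the sum.
#' @export
combined_total <- function(hq_results, map = selective_metabolite_map()) {
  selected <- hq_results[
    !is.na(map[hq_results$substance]) &
      map[hq_results$substance] == hq_results$metabolite_id, ]
  omitted <- setdiff(names(map), unique(selected$substance))
  if (length(omitted) > 0) {
    message("combined total: no HQ available for the selective metabolite of ",
            paste(omitted, collapse = ", "), "; omitted")
  }
  dup <- dplyr::count(selected, .data$country, .data$age_group,
                      .data$percentile, .data$substance)
  if (any(dup$n > 1)) {
    stop("a substance appears more than once in a population cell",
         call. = FALSE)
  }
  out <- dplyr::group_by(selected, .data$country, .data$age_group,
                         .data$percentile)
  dplyr::summarise(
    out,
    total_hq = sum(.data$hq),
    n_substances = dplyr::n(),
    components = list(dplyr::pick("substance", "metabolite_id", "hq")),
    .groups = "drop"
  )
}

#' Per-substance hazard quotients for measured biomonitoring aggregates
#'
#' Applies median (or otherwise chosen) allocation percentages to every
#' percentile of the measured urinary aggregates, converting each
#' (country, age group, metabolite, percentile) concentration into
#' per-substance attributed levels, and divides by the corresponding
#' guidance values derived from the registry at the chosen ADI vintage.
#' Substance-unique metabolites (a single registry link) are attributed 100%.
#'
#' @param hbm Measured aggregates: tibble with `country`, `age_group`,
#'   `metabolite_id`, `percentile`, `concentration` (µg/L).
#' @param contribution_table Output of [summarize_contributions()]; must
#'   contain the column named by `allocation_rank`.
#' @param reg A `pyr_registry`.
#' @param scenario Censoring scenario of the contribution table to use
#'   (default `"middle"`; the lower bound is of low relevance because all
#'   below-LOQ residues are zeroed there).
#' @param adi ADI vintage for the guidance values (default `"current"`).
#' @param allocation_rank Column of `contribution_table` giving the percent
#'   applied to every measured percentile (default `"p50"`).
#' @return Tibble with one row per (country, age_group, percentile,
#'   metabolite, substance): `percent`, `attributed_level`, `hbm_gv`, `hq`.
#' @export
assess_risk <- function(hbm, contribution_table, reg, scenario = "middle",
                        adi = c("current", "primo"), allocation_rank = "p50") {
  adi <- match.arg(adi)
  if (!allocation_rank %in% names(contribution_table)) {
    stop("contribution_table has no column '", allocation_rank, "'",
         call. = FALSE)
  }
  percents <- dplyr::transmute(
    contribution_table[contribution_table$scenario == scenario, ],
    metabolite_id = .data$metabolite_id,
    substance = .data$substance,
    age_class = .data$age_class,
    percent = .data[[allocation_rank]]
  )
  # single-source metabolites: full attribution, both age classes
  n_sources <- dplyr::count(reg$metabolites, .data$metabolite_id)
  unique_links <- dplyr::inner_join(
    reg$metabolites, n_sources[n_sources$n == 1, "metabolite_id"],
    by = "metabolite_id")
  if (nrow(unique_links) > 0) {
    pass_through <- tidyr::crossing(
      dplyr::select(unique_links, "metabolite_id", "substance"),
      age_class = c("adult", "child"), percent = 100
    )
    percents <- dplyr::bind_rows(
      dplyr::anti_join(percents, pass_through,
                       by = c("metabolite_id", "substance", "age_class")),
      pass_through
    )
  }
  gv <- dplyr::select(hbm_gv_table(reg, adi = adi), "substance",
                      "metabolite_id", "age_class", "hbm_gv")
  out <- dplyr::inner_join(
    dplyr::rename(hbm, age_class = "age_group"), percents,
    by = c("metabolite_id", "age_class"), relationship = "many-to-many"
  )
  out <- dplyr::inner_join(out, gv,
                           by = c("substance", "metabolite_id", "age_class"))
  out$attributed_level <- attribute_measured_level(out$concentration,
                                                   out$percent)
  out$hq <- hazard_quotient(out$attributed_level, out$hbm_gv)
  dplyr::select(
    dplyr::rename(out, age_group = "age_class"),
    "country", "age_group", "percentile", "metabolite_id", "substance",
    "percent", "attributed_level", "hbm_gv", "hq"
  )
}
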