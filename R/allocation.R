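#' Percent contribution of each substance to a shared metabolite
#'
#' Within each (metabolite, diet, year, scenario, age class) cell, the
#' contribution of a substance is its predicted urinary level as a percentage
#' of the summed level over all substances linked to that metabolite.
#' Substances linked to the metabolite in the registry but absent from the
#' predictions for a cell are completed with a zero level, i.e. counted as 0%
#' contributors (absence of quantified residues, not a missing measurement).
#' Cells whose total is zero yield `NA` percents and are excluded from
#' percentile summaries downstream.
#'
#' @param levels Per-substance predictions from [predict_levels()].
#' @param reg A `pyr_registry`; defines the complete set of substances linked
#'   to each metabolite.
#' @return Tibble of contribution records: `metabolite_id`, `substance`,
#'   `diet_id`, `year`, `scenario`, `age_class`, `concentration`, `percent`.
#'   Within each cell with positive total, percents sum to 100.
#' @export
contribution_percentages <- function(levels, reg) {
  if (any(levels$concentration < 0)) {
    stop("predicted concentrations must be >= 0", call. = FALSE)
  }
  links <- dplyr::select(reg$metabolites, "metabolite_id", "substance")
  cells <- dplyr::distinct(levels, .data$metabolite_id, .data$diet_id,
                           .data$year, .data$scenario, .data$age_class)
  full <- dplyr::left_join(
    dplyr::inner_join(cells, links, by = "metabolite_id",
                      relationship = "many-to-many"),
    dplyr::select(levels, "metabolite_id", "substance", "diet_id", "year",
                  "scenario", "age_class", "concentration"),
    by = c("metabolite_id", "substance", "diet_id", "year", "scenario",
           "age_class")
  )
  full$concentration[is.na(full$concentration)] <- 0
  out <- dplyr::mutate(
    dplyr::group_by(full, .data$metabolite_id, .data$diet_id, .data$year,
                    .data$scenario, .data$age_class),
    percent = {
      total <- sum(.data$concentration)
      if (total > 0) 100 * .data$concentration / total else
        rep(NA_real_, dplyr::n())
    }
  )
  dplyr::select(dplyr::ungroup(out), "metabolite_id", "substance", "diet_id",
                "year", "scenario", "age_class", "concentration", "percent")
}

#' Percentile summary of contribution percentages
#'
#' Pools the contribution records of all (diet, year) combinations within
#' each (metabolite, substance, age class, scenario) cell and reports the
#' requested percentiles. The default convention is inclusive linear
#' interpolation between order statistics ([stats::quantile()] type 7, the
#' common spreadsheet convention), under which the two-contributor
#' complementarity identity p_q(A) + p_(100-q)(B) = 100 holds exactly.
#'
#' @param contributions Output of [contribution_percentages()]. `NA` percents
#'   (zero-total cells) are dropped.
#' @param ranks Percentile ranks to report (default 10, 50, 90).
#' @param percentile_type Quantile convention for [stats::quantile()].
#' @return Tibble with `metabolite_id`, `substance`, `age_class`, `scenario`
#'   and one `p<rank>` column per requested rank. Cells with no non-missing
#'   record are dropped with a warning.
#' @export
summarize_contributions <- function(contributions, ranks = c(10, 50, 90),
                                    percentile_type = 7) {
  ok <- !is.na(contributions$percent)
  if (!all(ok)) {
    dropped <- contributions[!ok, ]
    n_cells <- nrow(dplyr::distinct(dropped, .data$metabolite_id,
                                    .data$diet_id, .data$year, .data$scenario))
    warning(n_cells, " zero-total cell(s) excluded from contribution ",
            "percentiles", call. = FALSE)
  }
  contributions <- contributions[ok, ]
  if (nrow(contributions) == 0) {
    stop("no non-missing contribution records to summarize", call. = FALSE)
  }
  out <- dplyr::reframe(
    dplyr::group_by(contributions, .data$metabolite_id, .data$substance,
                    .data$age_class, .data$scenario),
    rank = ranks,
    value = stats::quantile(.data$percent, probs = ranks / 100,
                            type = percentile_type, names = FALSE)
  )
  out$rank <- paste0("p", out$rank)
  tidyr::pivot_wider(out, names_from = "rank", values_from = "value")
}

#' Attribute a measured urinary level to one substance
#'
#' Applies a contribution percentage to a measured metabolite concentration:
#' `level * percent / 100`. Summed over all contributors of a cell with
#' same-cell percents, attribution partitions the measured level exactly.
#'
#' @param level Measured concentration, µg/L (>= 0, vectorised).
#' @param percent Contribution percentage in \[0, 100\].
#' @return Attributed concentration, µg/L.
#' @export
attribute_measured_level <- function(level, percent) {
  if (any(level < 0)) stop("level must be >= 0", call. = FALSE)
  if (any(percent < 0 | percent > 100)) {
    stop("percent must be in [0, 100]", call. = FALSE)
  }
  level * percent / 100
}

#' Parent-equivalent molar estimate from an attributed metabolite level
#'
#' Back-calculates the molar amount of parent compound implied by the share
#' of a measured metabolite concentration attributed to it: the attributed
#' mass concentration is converted to moles via the metabolite molecular
#' weight and corrected for incomplete molar excretion by dividing by Fue.
#' Units: µg/L divided by g/mol gives µmol/L.
#'
#' @inheritParams attribute_measured_level
#' @param mw_metabolite Metabolite molecular weight, g/mol.
#' @param fue Assumed molar urinary excretion fraction (> 0). If the true
#'   excretion fraction exceeds the assumed one, the estimate is inflated by
#'   the ratio true/assumed.
#' @return Parent-equivalent molar concentration, µmol/L.
#' @export
molar_parent_equivalent <- function(level, percent, mw_metabolite, fue) {
  if (any(fue <= 0)) {
    stop("fue must be > 0: a zero excretion fraction makes the parent-",
         "equivalent estimate undefined (no metabolite reaches urine)",
         call. = FALSE)
  }
  if (any(mw_metabolite <= 0)) stop("mw_metabolite must be > 0", call. = FALSE)
  attribute_measured_level(level, percent) / mw_metabolite / fue
}

#' Paired parent molar estimates from selective and generic metabolites
#'
#' For substances measured through both a selective metabolite (DCCA, CFMP
#' or DBCA) and the generic metabolite 3-PBA, back-calculates the median
#' parent-equivalent molar concentration of each population group twice:
#' once from the selective metabolite and once from 3-PBA, each using the
#' group's median measured level, the median allocation percentage and the
#' corresponding molecular weight and excretion fraction
#' (see [molar_parent_equivalent()]). Substance-unique metabolites are
#' attributed 100%. Agreement between the two routes probes the assumed
#' 3-PBA excretion fraction: a fraction assumed k-fold too low inflates the
#' 3-PBA-based estimates k-fold.
#'
#' @param hbm Measured aggregates (`country`, `age_group`, `metabolite_id`,
#'   `percentile`, `concentration`).
#' @param contribution_table Output of [summarize_contributions()] with a
#'   `p50` column.
#' @param reg A `pyr_registry`.
#' @param scenario Contribution scenario to use (default `"middle"`).
#' @param substances Substances to compare; defaults to every registry
#'   substance carrying both a 3PBA link and a selective metabolite.
#' @return Tibble with `country`, `age_group`, `substance`,
#'   `selective_based` and `pba_based` parent-equivalent estimates (µmol/L).
#' @export
cross_metabolite_estimates <- function(hbm, contribution_table, reg,
                                       scenario = "middle",
                                       substances = NULL) {
  map <- selective_metabolite_map()
  with_pba <- unique(reg$metabolites$substance[
    reg$metabolites$metabolite_id == "3PBA"])
  if (is.null(substances)) {
    substances <- intersect(names(map), with_pba)
  }
  percents <- dplyr::transmute(
    contribution_table[contribution_table$scenario == scenario, ],
    metabolite_id = .data$metabolite_id, substance = .data$substance,
    age_class = .data$age_class, percent = .data$p50
  )
  medians <- dplyr::rename(
    hbm[hbm$percentile == 50, c("country", "age_group", "metabolite_id",
                                "concentration")],
    age_class = "age_group")
  one_route <- function(s, metabolite) {
    link <- metabolite_link(reg, s, metabolite)
    pct <- percents[percents$substance == s &
                      percents$metabolite_id == metabolite, ]
    levels <- medians[medians$metabolite_id == metabolite, ]
    if (nrow(pct) == 0) {
      # substance-unique metabolite: full attribution
      pct <- tibble::tibble(age_class = c("adult", "child"), percent = 100)
    }
    out <- dplyr::inner_join(levels, pct[, c("age_class", "percent")],
                             by = "age_class")
    out$estimate <- molar_parent_equivalent(out$concentration, out$percent,
                                            link$mw_metabolite, link$fue)
    out[, c("country", "age_class", "estimate")]
  }
  rows <- lapply(substances, function(s) {
    sel <- one_route(s, map[[s]])
    pba <- one_route(s, "3PBA")
    merged <- dplyr::inner_join(
      dplyr::rename(sel, selective_based = "estimate"),
      dplyr::rename(pba, pba_based = "estimate"),
      by = c("country", "age_class"))
    merged$substance <- s
    merged
  })
  dplyr::select(dplyr::rename(dplyr::bind_rows(rows),
                              age_group = "age_class"),
                "country", "age_group", "substance", "selective_based",
                "pba_based")
}

#' Regression of selective-metabolite-based on generic-metabolite-based
#' molar estimates
#'
#' Ordinary least squares, intercept included, of parent molar estimates
#' derived from a substance's selective metabolite (DCCA, CFMP or DBCA;
#' response) on those derived from the generic metabolite 3-PBA (predictor),
#' across population groups. If the 3-PBA estimates are inflated by an
#' excretion fraction assumed too low by a factor k, the expected slope is
#' 1/k (0.2 for a five-fold under-assumption). Orientation is flippable via
#' `response`.
#'
#' @param data Tibble of paired estimates.
#' @param x,y Names of the predictor and response columns (defaults
#'   `"pba_based"` and `"selective_based"`).
#' @param response Which column plays the response: `"selective"` (default)
#'   regresses selective-based on 3-PBA-based; `"pba"` flips the orientation.
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
cross_metabolite_regression <- function(data, x = "pba_based",
                                        y = "selective_based",
                                        response = c("selective", "pba")) {
  response <- match.arg(response)
  if (response == "pba") {
    tmp <- x
    x <- y
    y <- tmp
  }
  xv <- data[[x]]
  yv <- data[[y]]
  if (length(xv) < 3) stop("need at least 3 paired points", call. = FALSE)
  if (stats::var(xv) <= .Machine$double.eps * mean(xv)^2) {
    stop("predictor has (near-)zero variance: fit undefined", call. = FALSE)
  }
  fit <- stats::lm(yv ~ xv)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       n = length(xv))
}
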