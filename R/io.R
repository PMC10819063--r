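.detect_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", header)) "\t" else ","
}

.read_delim_chr <- function(path) {
  readr::read_delim(path, delim = .detect_delim(path),
                    col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, show_col_types = FALSE, trim_ws = TRUE)
}

.require_columns <- function(df, required, path) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("'", path, "' is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
}

# Strict numeric parsing: decimal separator is ".", UTF-8; European comma
# decimals are rejected rather than silently mangled.
.parse_number <- function(x, field, line) {
  err <- character(0)
  has_comma <- grepl(",", x, fixed = TRUE)
  value <- suppressWarnings(as.numeric(x))
  bad <- has_comma | is.na(value)
  reason <- ifelse(has_comma,
                   paste0(field, " uses a comma decimal separator"),
                   paste0(field, " is not numeric"))
  if (any(bad)) {
    err <- sprintf("line %d: %s ('%s')", line[bad], reason[bad], x[bad])
    value[bad] <- NA_real_
  }
  list(value = value, errors = err)
}

.row_report <- function(errors, path, skip_invalid) {
  if (length(errors) == 0) return(invisible(NULL))
  report <- paste0("- ", errors, collapse = "\n")
  if (!skip_invalid) {
    stop(length(errors), " invalid row(s) in '", path, "':\n", report,
         "\nrerun with skip_invalid = TRUE to drop them", call. = FALSE)
  }
  warning("dropped ", length(errors), " invalid row(s) from '", path, "':\n",
          report, call. = FALSE)
}

#' Read a diet-level dietary risk table
#'
#' Reads a delimited text file (comma or tab, auto-detected from the header
#' line) of dietary exposure records with columns `diet_id`, `diet_label`,
#' `year`, `substance`, `scenario` (lower/middle/upper) and `percent_adi`
#' (exposure as percent of the ADI). Column order is irrelevant; extra
#' columns are ignored. Row-level failures (non-numeric or negative
#' `percent_adi`, comma decimal separators, unknown scenario, malformed
#' year) are collected with their file line numbers; the read aborts with
#' the full report unless `skip_invalid = TRUE`, which drops the offending
#' rows with a warning instead.
#'
#' @param path Input file path.
#' @param skip_invalid Drop invalid rows instead of aborting.
#' @return Tibble of validated records. Dropped-row reports are attached as
#'   attribute `"row_errors"`.
#' @export
read_diet_exposures <- function(path, skip_invalid = FALSE) {
  df <- .read_delim_chr(path)
  .require_columns(df, c("diet_id", "diet_label", "year", "substance",
                         "scenario", "percent_adi"), path)
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  errors <- character(0)

  pa <- .parse_number(df$percent_adi, "percent_adi", line)
  errors <- c(errors, pa$errors)
  neg <- !is.na(pa$value) & pa$value < 0
  errors <- c(errors, sprintf("line %d: percent_adi is negative (%s)",
                              line[neg], df$percent_adi[neg]))
  yr <- .parse_number(df$year, "year", line)
  errors <- c(errors, yr$errors)
  bad_scenario <- !df$scenario %in% c("lower", "middle", "upper")
  errors <- c(errors,
              sprintf("line %d: scenario must be lower/middle/upper ('%s')",
                      line[bad_scenario], df$scenario[bad_scenario]))
  bad <- is.na(pa$value) | neg | is.na(yr$value) | bad_scenario
  .row_report(errors, path, skip_invalid)

  out <- tibble::tibble(
    diet_id = df$diet_id[!bad], diet_label = df$diet_label[!bad],
    year = as.integer(yr$value[!bad]), substance = df$substance[!bad],
    scenario = df$scenario[!bad], percent_adi = pa$value[!bad]
  )
  attr(out, "row_errors") <- errors
  out
}

#' Write a diet-level dietary risk table
#'
#' Columns are written in the fixed documented order `diet_id`, `diet_label`,
#' `year`, `substance`, `scenario`, `percent_adi`.
#'
#' @param records Tibble of exposure records.
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_diet_exposures <- function(records, path, delim = ",") {
  readr::write_delim(
    records[, c("diet_id", "diet_label", "year", "substance", "scenario",
                "percent_adi")],
    path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Read aggregated urinary percentile tables
#'
#' Reads a delimited text file of aggregated human-biomonitoring data with
#' columns `country`, `age_group` (adult/child), `metabolite_id` (aliases
#' accepted), `percentile`, `concentration` and `unit` (must be `"ug/L"`,
#' alias `"µg/L"`). Within each (country, age group, metabolite) group,
#' concentrations must be nondecreasing in percentile rank; violating groups
#' are rejected with a warning naming the group, and the remaining groups
#' are returned.
#'
#' @inheritParams read_diet_exposures
#' @return Tibble with `country`, `age_group`, `metabolite_id`, `percentile`,
#'   `concentration` (µg/L).
#' @export
read_hbm_aggregates <- function(path, skip_invalid = FALSE) {
  df <- .read_delim_chr(path)
  .require_columns(df, c("country", "age_group", "metabolite_id",
                         "percentile", "concentration", "unit"), path)
  line <- seq_len(nrow(df)) + 1L
  errors <- character(0)

  unit_ok <- df$unit %in% c("ug/L", "µg/L", "μg/L")
  errors <- c(errors, sprintf("line %d: unit must be ug/L ('%s')",
                              line[!unit_ok], df$unit[!unit_ok]))
  age_ok <- df$age_group %in% c("adult", "child")
  errors <- c(errors, sprintf("line %d: age_group must be adult/child ('%s')",
                              line[!age_ok], df$age_group[!age_ok]))
  met <- tryCatch(canonical_metabolite(df$metabolite_id), error = function(e) NULL)
  met_ok <- if (is.null(met)) {
    toupper(df$metabolite_id) %in% names(.metabolite_aliases)
  } else {
    rep(TRUE, nrow(df))
  }
  errors <- c(errors, sprintf("line %d: unknown metabolite_id '%s'",
                              line[!met_ok], df$metabolite_id[!met_ok]))
  pc <- .parse_number(df$percentile, "percentile", line)
  cc <- .parse_number(df$concentration, "concentration", line)
  errors <- c(errors, pc$errors, cc$errors)
  rank_ok <- !is.na(pc$value) & pc$value > 0 & pc$value < 100
  conc_ok <- !is.na(cc$value) & cc$value >= 0
  errors <- c(errors, sprintf("line %d: percentile outside (0, 100)",
                              line[!is.na(pc$value) & !rank_ok]))
  errors <- c(errors, sprintf("line %d: concentration is negative",
                              line[!is.na(cc$value) & !conc_ok]))
  bad <- !unit_ok | !age_ok | !met_ok | !rank_ok | !conc_ok
  .row_report(errors, path, skip_invalid)

  out <- tibble::tibble(
    country = df$country[!bad], age_group = df$age_group[!bad],
    metabolite_id = canonical_metabolite(df$metabolite_id[!bad]),
    percentile = pc$value[!bad], concentration = cc$value[!bad]
  )
  out <- dplyr::arrange(out, .data$country, .data$age_group,
                        .data$metabolite_id, .data$percentile)
  mono <- dplyr::summarise(
    dplyr::group_by(out, .data$country, .data$age_group, .data$metabolite_id),
    ok = !is.unsorted(.data$concentration), .groups = "drop"
  )
  if (any(!mono$ok)) {
    bad_groups <- mono[!mono$ok, ]
    warning("rejected ", nrow(bad_groups), " group(s) with non-monotone ",
            "percentiles: ",
            paste(sprintf("%s/%s/%s", bad_groups$country,
                          bad_groups$age_group, bad_groups$metabolite_id),
                  collapse = ", "), call. = FALSE)
    out <- dplyr::anti_join(out, bad_groups,
                            by = c("country", "age_group", "metabolite_id"))
  }
  out
}

#' Write aggregated urinary percentile tables
#'
#' @param aggregates Tibble as returned by [read_hbm_aggregates()] (a `unit`
#'   column is added if absent).
#' @inheritParams write_diet_exposures
#' @return `path`, invisibly.
#' @export
write_hbm_aggregates <- function(aggregates, path, delim = ",") {
  if (!"unit" %in% names(aggregates)) aggregates$unit <- "ug/L"
  readr::write_delim(
    aggregates[, c("country", "age_group", "metabolite_id", "percentile",
                   "concentration", "unit")],
    path, delim = delim, progress = FALSE)
  invisible(path)
}
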