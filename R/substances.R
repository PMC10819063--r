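#' Canonical urinary metabolite identifiers
#'
#' The five pyrethroid urinary metabolites handled by the package, under their
#' canonical short identifiers. Several appear in the literature under more
#' than one abbreviation; [canonical_metabolite()] maps the common aliases
#' (CLF3CA for CFMP; 4-FPBA, 4-F3PBA, F-3-PBA for F3PBA; 3-PBA for 3PBA) onto
#' these identifiers.
#'
#' @format A character vector of length 5.
#' @export
METABOLITE_IDS <- c("DCCA", "DBCA", "CFMP", "3PBA", "F3PBA")

.metabolite_aliases <- c(
  "DCCA"    = "DCCA",
  "DBCA"    = "DBCA",
  "CFMP"    = "CFMP",
  "CLF3CA"  = "CFMP",
  "CIF3CA"  = "CFMP",
  "3PBA"    = "3PBA",
  "3-PBA"   = "3PBA",
  "F3PBA"   = "F3PBA",
  "F-3-PBA" = "F3PBA",
  "4-F3PBA" = "F3PBA",
  "4F3PBA"  = "F3PBA",
  "4-FPBA"  = "F3PBA"
)

#' Resolve metabolite identifier aliases
#'
#' @param x Character vector of metabolite identifiers or known aliases
#'   (case-insensitive).
#' @return Character vector of canonical identifiers (one of
#'   `r paste(METABOLITE_IDS, collapse = ", ")`).
#' @examples
#' canonical_metabolite(c("CLF3CA", "4-F3PBA", "3-pba"))
#' @export
canonical_metabolite <- function(x) {
  key <- toupper(trimws(as.character(x)))
  out <- unname(.metabolite_aliases[key])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown metabolite identifier(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Default parameter registry for the six pyrethroids
#'
#' Builds the registry of physico-chemical and toxicokinetic parameters used
#' throughout the package: for each active substance its molecular weight, the
#' acceptable daily intake (ADI, mg/kg bw/day) in two vintages (the value in
#' force when the dietary risk estimations were produced, `adi_primo`, and the
#' most recent value, `adi_current`, used for risk characterisation), and its
#' urinary metabolite links (metabolite molecular weight and molar urinary
#' excretion fraction Fue). Bifenthrin carries a single metabolite link (CFMP);
#' every other substance carries two (one acid-moiety, one alcohol-moiety
#' metabolite).
#'
#' The revised permethrin ADI of 0.01 mg/kg bw/day is stored as its
#' `adi_current`; for the other substances `adi_current` defaults to
#' `adi_primo` and can be overridden via a registry config file
#' (see [read_registry()]).
#'
#' The body-weight-adjusted daily urinary excretion defaults (`U`, L/kg
#' bw/day) are 0.0299 for adults and 0.0197 for children. These are
#' calibrated values, chosen so that permethrin at an ADI of 0.01 mg/kg
#' bw/day yields guidance values of 64 (adults) and 97 (children) µg DCCA/L
#' urine; they are not independently sourced physiological constants and are
#' overridable.
#'
#' @return An object of class `pyr_registry`: a list with tibbles
#'   `substances` (substance, mw_parent, adi_primo, adi_current),
#'   `metabolites` (substance, metabolite_id, mw_metabolite, fue) and
#'   `population` (age_class, urinary_excretion).
#' @examples
#' reg <- default_registry()
#' substance_params(reg, "cypermethrin")
#' @export
default_registry <- function() {
  substances <- tibble::tribble(
    ~substance,           ~mw_parent, ~adi_primo, ~adi_current,
    "deltamethrin",       505.2,      0.01,       0.01,
    "cyfluthrin",         434.3,      0.01,       0.01,
    "cypermethrin",       416.3,      0.005,      0.005,
    "lambda-cyhalothrin", 449.9,      0.0025,     0.0025,
    "bifenthrin",         422.9,      0.015,      0.015,
    "permethrin",         391.2,      0.05,       0.01
  )
  metabolites <- tibble::tribble(
    ~substance,           ~metabolite_id, ~mw_metabolite, ~fue,
    "deltamethrin",       "DBCA",         298.0,          0.45,
    "deltamethrin",       "3PBA",         214.2,          0.09,
    "cyfluthrin",         "DCCA",         208.1,          0.36,
    "cyfluthrin",         "F3PBA",        232.2,          0.47,
    "cypermethrin",       "DCCA",         208.1,          0.36,
    "cypermethrin",       "3PBA",         214.2,          0.09,
    "lambda-cyhalothrin", "CFMP",         242.6,          0.21,
    "lambda-cyhalothrin", "3PBA",         214.2,          0.09,
    "bifenthrin",         "CFMP",         242.6,          0.21,
    "permethrin",         "DCCA",         208.1,          0.36,
    "permethrin",         "3PBA",         214.2,          0.09
  )
  population <- tibble::tibble(
    age_class = c("adult", "child"),
    urinary_excretion = c(0.0299, 0.0197)
  )
  new_registry(substances, metabolites, population)
}

new_registry <- function(substances, metabolites, population) {
  reg <- structure(
    list(substances = tibble::as_tibble(substances),
         metabolites = tibble::as_tibble(metabolites),
         population = tibble::as_tibble(population)),
    class = "pyr_registry"
  )
  validate_registry(reg)
}

#' Validate a parameter registry
#'
#' Checks the structural invariants of a `pyr_registry`: positive molecular
#' weights and ADIs, excretion fractions in (0, 1], 1-2 metabolite links per
#' substance, known metabolite identifiers, and positive urinary excretion
#' values for both age classes. Errors name the offending field.
#'
#' @param reg A `pyr_registry` object.
#' @return `reg`, invisibly unchanged, if valid.
#' @export
validate_registry <- function(reg) {
  s <- reg$substances
  m <- reg$metabolites
  p <- reg$population
  fail <- function(field, msg) {
    stop("invalid registry field '", field, "': ", msg, call. = FALSE)
  }
  if (anyDuplicated(s$substance)) fail("substance", "duplicate substance names")
  if (!all(s$mw_parent > 0)) fail("mw_parent", "must be > 0")
  if (!all(s$adi_primo > 0)) fail("adi_primo", "must be > 0")
  if (!all(s$adi_current > 0)) fail("adi_current", "must be > 0")
  if (!all(m$mw_metabolite > 0)) fail("mw_metabolite", "must be > 0")
  if (!all(m$fue > 0 & m$fue <= 1)) fail("fue", "must be in (0, 1]")
  if (!all(m$metabolite_id %in% METABOLITE_IDS)) {
    fail("metabolite_id",
         paste("unknown id(s):",
               paste(setdiff(m$metabolite_id, METABOLITE_IDS), collapse = ", ")))
  }
  if (!all(m$substance %in% s$substance)) {
    fail("metabolites.substance", "link to unknown substance")
  }
  n_links <- table(m$substance)
  if (any(n_links < 1 | n_links > 2)) {
    fail("metabolites", "each substance must carry 1-2 metabolite links")
  }
  if (!setequal(p$age_class, c("adult", "child"))) {
    fail("age_class", "population must cover exactly 'adult' and 'child'")
  }
  if (!all(p$urinary_excretion > 0)) fail("urinary_excretion", "must be > 0")
  invisible(reg)
}

#' @export
print.pyr_registry <- function(x, ...) {
  cat("<pyr_registry> ", nrow(x$substances), " substances, ",
      nrow(x$metabolites), " metabolite links\n", sep = "")
  print(dplyr::left_join(x$substances, x$metabolites, by = "substance"))
  cat("urinary excretion (L/kg bw/day): ",
      paste(sprintf("%s %.4f", x$population$age_class,
                    x$population$urinary_excretion), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Look up one substance's parameters
#'
#' @param reg A `pyr_registry`.
#' @param substance Substance name.
#' @return One-row tibble of parent parameters with the metabolite links
#'   nested in a `metabolites` list-column.
#' @export
substance_params <- function(reg, substance) {
  row <- reg$substances[reg$substances$substance == substance, ]
  if (nrow(row) == 0) {
    stop("substance '", substance, "' is not in the registry", call. = FALSE)
  }
  row$metabolites <- list(
    reg$metabolites[reg$metabolites$substance == substance,
                    c("metabolite_id", "mw_metabolite", "fue")]
  )
  row
}

#' Look up a substance-metabolite link
#'
#' @inheritParams substance_params
#' @param metabolite_id Metabolite identifier (aliases accepted).
#' @return One-row tibble with `mw_metabolite` and `fue`.
#' @export
metabolite_link <- function(reg, substance, metabolite_id) {
  metabolite_id <- canonical_metabolite(metabolite_id)
  link <- reg$metabolites[reg$metabolites$substance == substance &
                            reg$metabolites$metabolite_id == metabolite_id, ]
  if (nrow(link) == 0) {
    stop("substance '", substance, "' has no metabolite link for '",
         metabolite_id, "'", call. = FALSE)
  }
  link
}

#' Body-weight-adjusted daily urinary excretion for an age class
#'
#' @inheritParams substance_params
#' @param age_class `"adult"` or `"child"`.
#' @return Urinary excretion in L/kg bw/day.
#' @export
urinary_excretion <- function(reg, age_class) {
  age_class <- match.arg(age_class, c("adult", "child"))
  reg$population$urinary_excretion[reg$population$age_class == age_class]
}

#' Derive a human biomonitoring guidance value (HBM-GV Gen Pop)
#'
#' The guidance value is the urinary metabolite concentration expected for an
#' individual at steady dietary exposure equal to the ADI:
#' \deqn{HBM\text{-}GV = ADI \times Fue \times \frac{MW_{met}}{MW_{parent}}
#'   \times \frac{1000}{U}}
#' with the ADI in mg/kg bw/day, molecular weights in g/mol, U the
#' body-weight-adjusted daily urinary excretion in L/kg bw/day, and the factor
#' 1000 converting mg to µg. The returned value is unrounded; round to the
#' nearest integer for display. With the default registry, permethrin at its
#' revised ADI of 0.01 mg/kg bw/day gives 64 (adults) and 97 (children)
#' µg DCCA/L urine.
#'
#' @inheritParams metabolite_link
#' @param age_class `"adult"` or `"child"`.
#' @param adi Which ADI vintage to evaluate at: `"current"` (default, used for
#'   risk characterisation) or `"primo"` (the vintage underlying the dietary
#'   risk estimations).
#' @return Guidance concentration in µg metabolite per L urine (unrounded).
#' @examples
#' reg <- default_registry()
#' round(derive_hbm_gv(reg, "permethrin", "DCCA", "adult"))  # 64
#' round(derive_hbm_gv(reg, "permethrin", "DCCA", "child"))  # 97
#' @export
derive_hbm_gv <- function(reg, substance, metabolite_id, age_class,
                          adi = c("current", "primo")) {
  adi <- match.arg(adi)
  params <- substance_params(reg, substance)
  link <- metabolite_link(reg, substance, metabolite_id)
  adi_value <- if (adi == "current") params$adi_current else params$adi_primo
  u <- urinary_excretion(reg, age_class)
  adi_value * link$fue * (link$mw_metabolite / params$mw_parent) * 1000 / u
}

#' Table of guidance values for every substance-metabolite link
#'
#' @inheritParams derive_hbm_gv
#' @param reg A `pyr_registry`.
#' @return Tibble with one row per (substance, metabolite, age class) and an
#'   `hbm_gv` column in µg/L.
#' @export
hbm_gv_table <- function(reg, adi = c("current", "primo")) {
  adi <- match.arg(adi)
  links <- dplyr::left_join(reg$metabolites, reg$substances, by = "substance")
  grid <- tidyr::crossing(links, reg$population)
  adi_value <- if (adi == "current") grid$adi_current else grid$adi_primo
  dplyr::transmute(
    grid,
    substance = .data$substance,
    metabolite_id = .data$metabolite_id,
    age_class = .data$age_class,
    adi_vintage = .env$adi,
    hbm_gv = adi_value * .data$fue * (.data$mw_metabolite / .data$mw_parent) *
      1000 / .data$urinary_excretion
  )
}

#' Read a parameter registry from a YAML config file
#'
#' The config mirrors the registry structure:
#' ```yaml
#' substances:
#' - name: cypermethrin
#'   mw: 416.3
#'   adi_primo: 0.005
#'   adi_current: 0.005
#'   metabolites:
#'   - {id: DCCA, mw: 208.1, fue: 0.36}
#'   - {id: 3PBA, mw: 214.2, fue: 0.09}
#' population:
#'   adult: 0.0299
#'   child: 0.0197
#' ```
#' `adi_current` may be omitted (defaults to `adi_primo`); metabolite ids may
#' use any known alias. Validation failures name the offending field.
#'
#' @param path Path to the YAML file.
#' @return A `pyr_registry`.
#' @seealso [write_registry()] for the inverse; round-tripping is lossless.
#' @export
read_registry <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$substances)) {
    stop("invalid registry field 'substances': missing", call. = FALSE)
  }
  num_field <- function(entry, field, default = NULL) {
    v <- entry[[field]]
    if (is.null(v)) v <- default
    if (is.null(v) || !is.numeric(v)) {
      stop("invalid registry field '", field, "' for substance '",
           entry$name %||% "?", "': must be numeric", call. = FALSE)
    }
    v
  }
  substances <- dplyr::bind_rows(lapply(cfg$substances, function(s) {
    tibble::tibble(
      substance = as.character(s$name),
      mw_parent = num_field(s, "mw"),
      adi_primo = num_field(s, "adi_primo"),
      adi_current = num_field(s, "adi_current", default = s$adi_primo)
    )
  }))
  metabolites <- dplyr::bind_rows(lapply(cfg$substances, function(s) {
    dplyr::bind_rows(lapply(s$metabolites, function(m) {
      tibble::tibble(
        substance = as.character(s$name),
        metabolite_id = canonical_metabolite(m$id),
        mw_metabolite = num_field(m, "mw"),
        fue = num_field(m, "fue")
      )
    }))
  }))
  pop <- cfg$population %||% list(adult = 0.0299, child = 0.0197)
  population <- tibble::tibble(
    age_class = c("adult", "child"),
    urinary_excretion = c(pop$adult %||% 0.0299, pop$child %||% 0.0197)
  )
  new_registry(substances, metabolites, population)
}

#' Write a parameter registry to a YAML config file
#'
#' @param reg A `pyr_registry`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(reg, path) {
  subs <- lapply(seq_len(nrow(reg$substances)), function(i) {
    row <- reg$substances[i, ]
    links <- reg$metabolites[reg$metabolites$substance == row$substance, ]
    list(
      name = row$substance,
      mw = row$mw_parent,
      adi_primo = row$adi_primo,
      adi_current = row$adi_current,
      metabolites = lapply(seq_len(nrow(links)), function(j) {
        list(id = links$metabolite_id[j], mw = links$mw_metabolite[j],
             fue = links$fue[j])
      })
    )
  })
  pop <- as.list(stats::setNames(reg$population$urinary_excretion,
                                 reg$population$age_class))
  yaml::write_yaml(list(substances = subs, population = pop), path)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
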