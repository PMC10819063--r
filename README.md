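# pyrisk

Tiered retrospective risk assessment of pyrethroid insecticides from food
monitoring and human biomonitoring data.

Pyrethroids with very different toxic potencies are excreted as the *same*
urinary metabolites — DCCA from cyfluthrin, cypermethrin and permethrin;
CFMP (CLF3CA) from lambda-cyhalothrin and bifenthrin; the generic 3-PBA
from most of the group — so a measured urinary concentration cannot be
interpreted as risk until it is allocated to parent substances. `pyrisk`
is aimed at exposure and risk assessors working with aggregated human
biomonitoring data (percentile tables per country and age group, µg/L
urine) and diet-level dietary risk estimates (chronic exposure as % of the
acceptable daily intake, per national diet and year, with lower/middle/
upper bounds for residues below the limit of quantification).

The core model is a steady-state mass balance. The urinary concentration
of metabolite *m* expected from a daily dose *D* (mg/kg bw/day) of parent
substance *s* is

    C = D · Fue · (MW_m / MW_s) · 1000 / U      [µg/L]

with `Fue` the molar urinary excretion fraction, `MW_m/MW_s` the
metabolite-to-parent molecular weight ratio and `U` the body-weight
adjusted daily urinary excretion (L/kg bw/day). Evaluated at `D = ADI`
this gives the human biomonitoring guidance value (HBM-GV Gen Pop). On top
of this the package provides:

* **dosimetry** — predicted urinary levels and per-metabolite totals from
  %ADI exposure tables, paired against measured percentile curves;
* **allocation** — per-substance contribution percentages to each shared
  metabolite, percentile summaries (10/50/90, spreadsheet-convention
  quantiles), attribution of measured levels, and a cross-metabolite molar
  consistency analysis that exposes misspecified excretion fractions as a
  regression slope;
* **risk** — hazard quotients per substance, cumulative per metabolite,
  and a combined total over each substance's most selective metabolite
  (3-PBA-based quotients are excluded as over-conservative);
* **probabilistic** — distribution reconstruction from three reported
  percentiles over a six-family gallery, and a seeded Monte Carlo that
  propagates level and contribution variability to an exceedance
  probability;
* **synthetic data** — a generator for both input table families with
  known ground truth, so the full chain is testable offline.

## Worked example

```r
library(pyrisk)

reg <- default_registry()
round(derive_hbm_gv(reg, "permethrin", "DCCA", "adult"))  # 64 ug/L
round(derive_hbm_gv(reg, "permethrin", "DCCA", "child"))  # 97 ug/L

res <- run_pipeline(simulate = TRUE, seed = 1)
subset(res$contribution_table,
       scenario == "middle" & age_class == "child" &
         metabolite_id %in% c("DCCA", "CFMP"))
#>   metabolite_id          substance age_class scenario  p10  p50  p90
#> 1          CFMP         bifenthrin     child   middle 17.6 34.9 55.7
#> 2          CFMP lambda-cyhalothrin     child   middle 44.3 65.1 82.4
#> 3          DCCA         cyfluthrin     child   middle  6.5 14.4 23.8
#> 4          DCCA       cypermethrin     child   middle 44.8 62.1 77.6
#> 5          DCCA         permethrin     child   middle 12.8 22.3 37.5
```

The contribution table reads: in the middle censoring scenario,
cypermethrin accounts for a median 62% of the DCCA predicted for
children's diets (10th–90th percentile 45–78% across diets and years), and
lambda-cyhalothrin for a median 65% of CFMP — with the bifenthrin row its
exact complement, a structural identity of two-contributor cells under the
inclusive percentile convention.

```r
dplyr::arrange(res$cumulative, -cumulative_hq)[1, ]
#>   country age_group percentile metabolite_id cumulative_hq n_substances
#> 1    SY05     adult         95          3PBA          1.14            4
res$mc$result$exceedance   # P(total HQ > 1) for that group: 0.0894
res$mc$fits[, c("role", "substance", "family")]
#>           role          substance     family
#> 1        level               <NA>  lognormal
#> 2 contribution       cypermethrin triangular
#> 3 contribution       deltamethrin triangular
#> 4 contribution lambda-cyhalothrin  lognormal
#> 5 contribution         permethrin triangular
```

The deterministic worst case here is the 95th percentile of 3-PBA in one
synthetic adult population (cumulative HQ 1.14, driven by the deliberately
conservative 3-PBA excretion fraction of 0.09); the Monte Carlo stage
refits that group's reported percentiles and contribution spreads and puts
the probability of the total hazard quotient exceeding 1 at about 9%.
Hazard quotients from the *selective* metabolites, which carry the
combined-risk conclusion, stay below 1 throughout.

A thin command-line wrapper over the same functions ships in
`inst/cli/pyrisk.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","pyrisk.R",package="pyrisk"))')" \
    all --seed 1 --output-dir out --verbose
```

Subcommands `simulate`, `predict`, `allocate`, `attribute`, `risk`,
`montecarlo` and `all` write the stage tables plus a machine-readable
`run_summary.json` (seed, registry hash, ADI vintages, row counts); reruns
with the same configuration and seed are byte-identical.

## Documentation

The methods vignette
(`vignettes/pyrethroid-risk-refinement.Rmd`) documents the model and its
assumptions, the calibrated parameters, the percentile and tie-breaking
conventions, the identifiability limits of three-anchor distribution
fitting, and what the synthetic generator does and does not emulate.
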