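---
title: "Retrospective pyrethroid risk refinement: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrospective pyrethroid risk refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyrisk)
```

## The problem

Human biomonitoring measures pyrethroid exposure through urinary metabolites,
but the metabolites are shared: DCCA is excreted after intake of cyfluthrin,
cypermethrin or permethrin; CFMP (also written CLF3CA) after
lambda-cyhalothrin or bifenthrin; and the generic 3-PBA after most
phenoxybenzyl pyrethroids. Because the parent substances differ strongly in
toxic potency, a measured metabolite concentration cannot be converted into
a health-referenced risk figure until it has been *allocated* to parent
substances. `pyrisk` implements a tiered workflow that uses EU-wide food
monitoring results — chronic dietary exposure per national diet, expressed
as a percentage of each substance's acceptable daily intake (ADI) — to
quantify those allocations, and then characterises risk against human
biomonitoring guidance values, deterministically and probabilistically.

## Forward dosimetry

The central mass balance assumes steady-state daily intake and first-order
urinary elimination. For a parent dose $D$ (mg/kg bw/day) the expected
urinary concentration of a metabolite is

$$
C \;=\; D \times F_{ue} \times \frac{MW_{met}}{MW_{parent}}
        \times \frac{1000}{U} \qquad [\mu g/L],
$$

where $F_{ue}$ is the molar urinary excretion fraction (mol metabolite
excreted per mol parent ingested), the molecular-weight ratio converts
parent mass to metabolite mass, $U$ is the body-weight-adjusted daily
urinary excretion (L/kg bw/day), and the factor 1000 converts mg to µg.
Dietary risk model outputs give exposure as %ADI, so
$D = \%ADI \times ADI / 100$. Evaluating the mass balance at $D = ADI$
yields the human biomonitoring guidance value (HBM-GV Gen Pop): the urinary
level expected at steady exposure exactly at the ADI. The %ADI shortcut
`predict_via_hbm_gv()` is algebraically identical to the two-step path and
the package asserts their agreement to within 1e-9 relative tolerance.

### Parameters and units

| parameter | units | default | notes |
|---|---|---|---|
| ADI (two vintages) | mg/kg bw/day | registry values | `adi_primo` is the vintage the dietary %ADI figures were computed against and drives dosimetry; `adi_current` is the most recent value and drives risk characterisation. They differ only for permethrin (0.05 vs 0.01). |
| $F_{ue}$ | – | registry values | per substance–metabolite link; the 3-PBA value of 0.09 is deliberately conservative. |
| $MW$ | g/mol | registry values | parent and metabolite. |
| $U$, adult | L/kg bw/day | 0.0299 | **calibrated**, see below. |
| $U$, child | L/kg bw/day | 0.0197 | **calibrated**, see below. |

The urinary excretion defaults are *calibrated, not sourced*: no value of
$U$ is printed alongside the parameter table this registry reproduces, so
the defaults were solved backwards such that permethrin at an ADI of
0.01 mg/kg bw/day yields guidance values of 64 (adults) and 97 (children)
µg DCCA/L urine. Both are exposed in the registry config
(`inst/extdata/registry.yaml`) and can be overridden. All guidance values
are kept unrounded internally; display rounding is to the nearest integer
µg/L, which is how the 64/97 pair is conventionally quoted.

Diet labels are free text; `classify_diet()` assigns any label containing
an infant/toddler/child token (case-insensitive) to the children's guidance
values and everything else — including diets marked "general" — to the
adults'. The token list is user-extensible.

## Allocation of shared metabolites

For every (metabolite, diet, year, scenario) cell the package predicts the
per-substance urinary contribution and expresses it as a percentage of the
cell total. Substances linked to the metabolite in the registry but absent
from the food data are counted as 0% contributors — absence of quantified
residues is information, not missingness — whereas cells with zero total
produce missing records that are excluded from summaries. Percentiles
(10/50/90 by default) are pooled over all (diet, year) combinations within
age class and scenario.

The percentile estimator is inclusive linear interpolation between order
statistics (`stats::quantile(type = 7)`), the convention of common
spreadsheet software. It was chosen because it preserves the
two-contributor complementarity identity
$p_q(A) + p_{100-q}(B) = 100$ exactly — visible in the CFMP column of
allocation tables, where the cyhalothrin and bifenthrin rows mirror each
other. The estimator is configurable (`percentile_type`).

The middle censoring-bound scenario is the default for all allocation and
risk outputs. The lower bound treats every below-LOQ residue as zero, which
degenerates contribution shares whenever a substance's residues are fully
censored; it is computed but flagged as low-relevance. Upper-bound shares
are nearly identical to middle-bound ones because the common censored-mass
factor cancels inside a ratio.

### Cross-metabolite consistency and the 3-PBA excretion fraction

For substances carrying both a selective metabolite (DCCA, CFMP, DBCA) and
3-PBA, the median measured level of each population group can be
back-calculated to a parent molar equivalent twice:
$(C \cdot pct/100) / MW_{met} / F_{ue}$, in µmol/L. If the assumed 3-PBA
excretion fraction is $k$-fold lower than the true one, the 3-PBA-based
estimates are inflated $k$-fold, and an ordinary least squares fit of
selective-based on 3-PBA-based estimates has expected slope $1/k$. The
regression orientation is flippable (`response = "pba"`); the default
orientation makes a five-fold under-assumption appear as a slope of
0.09/0.45 = 0.2. The two published statements about this comparison (3-PBA
estimates "consistently lower" vs a five-fold-higher fraction reconciling
them) are not mutually consistent; the package documents both orientations
and does not attempt to resolve the intent.

## Risk characterisation

Hazard quotients divide each attributed level by the corresponding guidance
value at the *current* ADI vintage. Three aggregations are provided:

* per-substance HQ for every (country, age group, percentile, metabolite);
* cumulative HQ per shared metabolite (plain sum over its contributors);
* combined total across substances, where each substance enters exactly
  once through its most selective metabolite: DBCA for deltamethrin, F3PBA
  for cyfluthrin, DCCA for cypermethrin and permethrin, CFMP for
  lambda-cyhalothrin and bifenthrin. 3-PBA never enters the combined
  total: its conservative excretion fraction makes 3-PBA-derived HQs
  unrealistically high. Cyfluthrin still contributes its DCCA share to the
  DCCA cumulative HQ; only the combined total restricts it to F3PBA, which
  avoids double counting without discarding the per-metabolite aggregate.

In deterministic mode every measured percentile is paired with the median
(p50) allocation percentage; propagating allocation variability is the job
of the probabilistic stage. Whether a published deterministic figure paired
measured percentiles with median or scenario-matched allocation percentiles
is not stated anywhere we could check; the p50 pairing is the documented
default.

## Probabilistic refinement

Aggregated biomonitoring data arrive as percentiles, not samples.
`fit_from_percentiles()` reconstructs a full distribution from three
anchors (5/50/95 for population levels, 10/50/90 for contribution
percentages) by minimising the sum of squared *relative* quantile
deviations over a six-family gallery (gamma, lognormal, Weibull, normal,
uniform, triangular). Relative rather than absolute deviations keep the
uppermost anchor of a heavy-tailed level distribution from dominating the
objective; the absolute form is available via `objective = "absolute"`.

Numerical choices:

* Parameters are optimised on unconstrained scales (log transforms for
  positivity, increment parameterisation `min < mode < max` for the
  triangular) with Nelder–Mead plus a restart; initialisation is by
  closed-form quantile matching per family, which is already exact for the
  normal, lognormal and uniform.
* Objectives below 1e-12 are treated as exact fits and ties are broken by
  the fixed gallery order above. The three-parameter triangular can
  interpolate almost any anchor triple exactly, so it is deliberately
  *last*: it wins only when no simpler family fits.
* **Identifiability.** Three anchors do not always identify the family.
  Any symmetric anchor triple is fitted exactly by every symmetric
  location-scale family: the 5/50/95 quantiles of a uniform are also exact
  normal quantiles, so a uniform is reported as the (anchor-equivalent)
  normal. This is a mathematical degeneracy of percentile-only
  information, not an optimiser failure; tests assert family and parameter
  recovery for the identifiable cases and anchor-exactness for the
  degenerate one.
* A triangular fit of a nonnegative quantity whose implied minimum is
  negative is refitted with the minimum pinned to zero, with a warning.
* Degenerate (point-mass) distributions are available via
  `point_distribution()` and turn the Monte Carlo into the deterministic
  pipeline exactly — a useful consistency check.

`run_monte_carlo()` draws, per iteration, a population level and one
contribution percentage per substance (clipped to [0, 100]; a clipping
fraction above 0.5% triggers a warning). Contributions are sampled
independently per substance, matching the per-substance fitted
distributions; renormalisation onto the 100% simplex is an explicit flag
because a joint model of the shares is not specified by the underlying
method. The random stream order is fixed and documented — level vector
first, then each substance's contribution vector in list order — so a
fixed seed yields bit-identical results. Default 10,000 iterations; the
exceedance probability is reported against a configurable total-HQ
threshold (default 1).

## The synthetic-data generator

`generator_config()` / `generate_primo_table()` / `generate_hbm_table()`
emulate the *shapes* of the two real input families: diet-level dietary
risk tables with three LOQ-censoring bounds, and per-country aggregated
urinary percentile tables. They exist so that every pipeline stage is
testable end-to-end with known ground truth and no external downloads.

What it emulates:

* 36 diets × 2016–2020, with every fourth diet labelled as a children's
  diet (toddler/child/infant tokens);
* true doses lognormal across (diet, year) with configurable inter-diet
  sigma; a configurable fraction of residue mass below the LOQ generates
  lower/middle/upper bounds as 0, half, and full substitution of the
  censored mass, so the bound ordering holds by construction;
* population urinary levels lognormal around the steady-state median
  implied by the true doses and *generation-side* excretion fractions
  (`true_fue` overrides let the truth differ from the analysis values —
  the mechanism behind the misspecification experiments);
* synthetic countries as replicate draws of the same generating process at
  different overall exposure multipliers, plus optional multiplicative
  measurement noise on reported medians.

What it does not emulate: commodity-level residue data (censoring is
modelled on the diet-aggregated %ADI mass, matching the shape of the real
inputs), real national diet composition (an exploratory check in the
source analysis found country-by-country matching unsupported), creatinine
adjustment or urine dilution, and correlation between dietary level and
contribution shares. Passing tests therefore demonstrate internal
consistency of the method chain, not fidelity to any particular country's
data.

Default calibration (chosen once, as the study conditions): median doses
of 8.0e-5 (cyfluthrin), 4.0e-4 (cypermethrin), 1.0e-4 (permethrin),
3.2e-4 (deltamethrin), 1.2e-4 (lambda-cyhalothrin) and 5.6e-5 (bifenthrin)
mg/kg bw/day. These reproduce the reported contribution structure — a
cypermethrin-led DCCA split of roughly 13/66/17 and a CFMP split of
roughly 67/33 — at exposures well below the ADIs, giving children's DCCA
medians of a few µg/L and 95th-percentile cumulative HQs around 0.2, i.e.
the documented scale of the real assessment. Inter-diet sigma defaults to
0.5 (a geometric spread comparable to the wide reported p10–p90
contribution ranges), censored mass fraction to 0.5 (measured levels sit
between the lower and middle bounds), population geometric SD to 2.0 (a
typical spot-urine biomarker spread), inter-country geometric SD to 1.5,
and measurement noise to 0.

### Two notions of ground truth

`generate_primo_table()` returns both configuration-level shares (the
plug-in contribution shares implied by the median doses; they sum to 1 per
metabolite) and *realized* shares (the median per-age-class share of the
doses actually drawn). The distinction matters statistically. The share of
one substance in a ratio of independent lognormals is a nonlinear
statistic: its population median sits up to about one percentage point
below the plug-in share at sigma 0.5 for metabolites with three or more
contributors, and the sampling SE of a per-age-class median at the default
problem size is 1.4 points (adults, 135 cells) to 2.8 points (children,
45 cells). A ±2-point comparison of estimated p50 against *plug-in* shares
at sigma 0.5 therefore fails for essentially every seed, for purely
statistical reasons. The package's end-to-end recovery check consequently
compares the pipeline's p50 against the generator's *realized* shares —
which validates everything the pipeline actually does to the data
(%ADI encoding, ADI vintages, censoring scenarios, unit conversions,
percentile convention) — and checks plug-in recovery at sigma 0.2, where
the ±2-point band is a genuine accuracy statement (SE well under one
point). Both comparisons live in the test suite.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
the default study size (36 diets × 5 years × 6 substances × 3 scenarios ≈
3,240 exposure records), with 20 synthetic countries for the
misspecification experiments in the tests and 50 in the acceptance script
(50 countries × 2 age groups × 4 substances = 400 regression points, which
keeps the OLS slope stable to a few percent across seeds), and 10,000
Monte Carlo iterations. A full pipeline run at these sizes takes a few
seconds.

## Known limitations

* The urinary excretion defaults are reverse-calibrated, not measured; any
  error in them rescales all guidance values and predicted levels
  proportionally (it cancels in contribution percentages).
* Allocation percentages are applied to measured percentiles as if share
  and level were independent; the deterministic p50 pairing understates
  tail variability, which is why the Monte Carlo stage exists.
* The distribution gallery is percentile-matched, not likelihood-fitted;
  with three anchors the family label is not always identifiable (see
  above), and no goodness-of-fit beyond the anchor deviations is claimed.
* Cumulative risk is plain HQ summation; relative-potency weighting and
  dose-addition frameworks are out of scope.
* National-diet-to-country matching is deliberately not attempted; all
  diets are pooled as an exposure distribution, separated only by age
  class.
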