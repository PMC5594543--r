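---
title: "Methods: simulating and analyzing PM10 effects on EV-miRNAs and coagulation"
author: "evmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing PM10 effects on EV-miRNAs and coagulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evmir)
```

## The scientific problem

Short-term exposure to particulate matter (PM10) is associated with
cardiovascular events, plausibly through a pro-coagulant response. One
candidate messenger is the plasma extracellular vesicle (EV): cells release
EVs carrying microRNAs, and the EV count and its miRNA cargo may shift
within a day of a pollution episode. The analytical chain this package
implements connects four questions for a panel of overweight/obese adults:

1. Is the previous day's PM10 associated with plasma EV counts (total by
   nanoparticle tracking, and by cell-of-origin surface markers)?
2. Which EV-miRNAs respond to Day −1 PM10, using a two-stage
   screening/validation design on an RT-qPCR (OpenArray-style) panel?
3. Is the PM10–fibrinogen association mediated by the responding miRNAs?
4. Do the responding miRNAs plausibly target cardiovascular-disease genes?

No individual-level data from such studies are deposited publicly, so the
package is organized around a synthetic-cohort generator that plants known
effects. Every analysis stage is then validated by *parameter recovery*:
simulate under a planted truth, run the stage exactly as on real data, and
check the estimate against the truth. `tests/testthat/test-acceptance.R`
and `scripts/acceptance.R` are the formalization of that protocol.

## Exposure model and assignment

Daily log PM10 per monitor is a sum of a fixed annual cosine (winter peak,
amplitude 0.25 on the log scale by default), a calendar-year random level
(SD 0.08), a monitor siting offset (SD 0.12), and a stationary AR(1)
process (lag-1 correlation 0.6, marginal SD 0.45), exponentiated around an
annual geometric mean of 40 µg/m³ — magnitudes typical of a polluted
southern-European airshed, with realistic winter episodes above
100 µg/m³. Temperature and relative humidity follow an annual cycle with
daily noise, feeding the apparent-temperature covariate.

Subjects receive Day 0 exposure from the monitor nearest the clinic and
Days −1…−7 plus the 182/365-day long-term means (windows ending at Day −1)
from the monitor nearest their residence. Distances are planar Euclidean:
the synthetic coordinates are planar and at a ~100 km regional scale the
geodesic correction is irrelevant; the metric lives in one small function
(`nearest_monitor()`) should a geodesic variant ever be needed. A grid-cell
assignment (`assign_grid_cell()`, half-open 4-km cells) is provided for
chemical-transport-model style exposure; missing monitor-days raise an
error naming the subject and date rather than being imputed.

Apparent temperature is the Steadman/Kalkstein form
`AT = −2.653 + 0.994·T + 0.0153·Td²` with the Magnus dew point. One
behaviour worth knowing: because the dew-point term is squared, AT is
monotone in humidity only where Td ≥ 0 °C; in very dry air it turns
around. The formula is standard in air-pollution epidemiology and is kept
as is; it is implemented as a swappable function.

## Cohort and outcome generation

Covariate marginals are fixed to the emulated study population: age
truncated-normal 52.4 ± 13.8 above 18 years; 73.1% female; smoking
48.7/35.3/15.8% never/former/current; BMI ≥ 25 with the overweight
(25–30) share allocated *exactly* at 26.9% (rounded), so BMI-stratified
scenarios have deterministic stratum sizes; enrollment dates weighted to
an autumn/winter-heavy calendar. Joint covariate correlations are not
modeled — the sources report only marginals — and this is a documented
simplification, not an inference.

Outcomes follow log-linear models with centered covariates:

* `ln(EV_m) = α_m + β_m·PM10(Day −1) + β_m_yr·PM10(yearly) + covariates + N(0, 0.5)`
* `ln(fibrinogen) = γ₀ + γ_PM10·PM10(Day −1) + Σ γ_M·M + covariates + N(0, 0.17)`

EV counts are lognormal because such counts are right-skewed and the
analysis log-transforms them; the fibrinogen noise SD 0.17 reproduces the
reference interquartile range (median 325, Q1–Q3 290–366 mg/dl). β may be
stratum-specific (`c(overweight=, obese=)`) so interaction models have a
planted truth. Effects are planted per 1 µg/m³; `beta_from_delta()`
converts printed percent changes per 10 µg/m³ — `(e^{10β}−1)·100` for ln
outcomes, `(2^{10β}−1)·100` for log2 outcomes — into slopes exactly.

The Crt panel: true log2 expression is `a_j + s_i + b_j·PM10c + e_ij` with
assay baselines `a_j ~ U(−1, 8)` (spanning the expressed-in-≥50% gate),
a subject RNA-content offset `s_i` (SD 0.2 cycles), planted slopes `b_j`,
and well noise (SD 0.8 cycles). Crt is `28 − x`, clipped below at 10, so
the Crt > 28 rule lands naturally on "undetectable". Exactly
`round(frac_never_amplified · n_assays)` non-planted assays are missing in
every subject (seeded sampling without replacement, reproducible), and 2%
of wells get an AmpScore below 1.1. Endogenous controls are stable,
high-expression assays (noise SD 0.15 cycles — abundant templates
amplify precisely); the exogenous spike-in lacks `s_i` because it is added
at fixed quantity per reaction.

`plant_mediation()` defines each mediator M as the *control-pair
normalized* log2 expression — computed with the same QC → exclusion →
normalization path the analysis uses — so the generative mediator and the
analyzed mediator are the same variable and the planted decomposition
`total = γ_PM10 + Σ β·γ` holds exactly in the fitted models' expectation.
Had M been defined on raw expression, global-mean or control
normalization would attenuate each planted slope by the mean planted
slope over retained assays (a ~1/545 effect at screening scale; stated
here for users who repurpose the generator).

Two generator choices deserve emphasis because they interact with the
mediation stage. First, the shared content offset `s_i` and the shared
control-pair noise are common factors across *all* normalized mediators:
with large values they induce cross-mediator correlation, and a
single-mediator product-of-coefficients model then shows spurious
outcome paths for non-mediating candidates. The defaults (0.2 and 0.15
cycles) keep this shared-normalizer channel small; the phenomenon itself
is real and is a known limit of single-mediator models on ratio-normalized
panels, which is why it is documented rather than hidden. Second, in the
mediated-flag scenario the four non-mediating candidates are fully null
(no PM10 path, no outcome path): a candidate with a strong PM10 path but
a null outcome path faces the product test's one-path-null behaviour
(~5% or more false flags), and no configuration with such candidates can
keep "exactly five flags" stable across replicates.

## Preprocessing: QC, exclusion, normalization, stability

The cleaning rule is total and idempotent: Crt > 28, AmpScore < 1.1, or a
missing value makes a well unamplified, Crt := 29. Assays amplified in no
subject are then excluded; the fixed order QC → exclusion → normalization
is asserted by the API (normalization refuses un-QC'd panels).

Expression is the relative quantification `2^−ΔCrt`. The global-mean
normalizer averages each subject's *amplified* wells over retained
non-control assays: including the imputed 29s would shift subject means by
their own unamplified-well count, which is exactly the artifact
normalization should remove, and the sources do not state the contrary
convention. Unamplified wells propagate the floor value
`2^−(29 − r_i)` rather than NA, so downstream matrices stay complete. The
validation-phase strategy is the arithmetic mean Crt of an endogenous and
an exogenous control — the symmetric reading of "combining" the two — as
a subject-wise reference; a subject whose reference assay is unamplified
is a reported normalization failure, not a silent drop.

Stability scoring treats each candidate strategy's subject-wise normalizer
as a pseudo reference gene. geNorm's `M_j` is the mean SD of pairwise
log-ratios to the other candidates; NormFinder's ungrouped stability is
the per-candidate variance of doubly centered residuals (with groups, an
intra/inter variance combination). Candidates are ranked by mean rank of
the two scores. NormFinder runs ungrouped by default because no grouping
variable is specified for the emulated design.

## Association models

All models are OLS with the a priori covariates age, sex, BMI, smoking
and Day −1 apparent temperature; other candidate confounders can be added
via `model_spec()` but are excluded from defaults. Categorical covariates
use indicator contrasts with the alphabetically first level as reference
(deterministic across inputs). Exposure is coded per 1 µg/m³; the ×10
scaling lives only in the Δ% transform, so there is exactly one place a
scaling bug could exist and it is round-trip tested to 1e−10. Wald CI
endpoints map through the same monotone transform, which is why Δ% CIs
are asymmetric. Missing data are complete-case with dropped counts
reported.

Screening fits one model per assay through a shared design matrix (QR
once, all assays solved jointly — numerically identical to per-assay
`lm()`, and tested to be). BH FDR runs across all successfully tested
assays; an assay whose fit is degenerate (e.g. constant expression; the
criterion is a relative residual floor, since a constant column leaves
~1e−30 numerical residuals) is reported and skipped without aborting the
run. Top-k selection filters to assays expressed in ≥ 50% of subjects and
orders by ascending raw p — "most associated" is read as smallest p —
with ties broken by |Δ%| descending, then assay id, fixed for determinism.
Validation declares raw p < 0.05.

Stratified models drop BMI from the covariates (it is the stratifying
variable); the interaction p is the Wald p of the
`bmi_category × exposure` product term in the pooled model with
`bmi_category` as a main effect.

One emergent subtlety, visible in `analysis/03_associations.R`: if both a
short-term and a long-term channel are planted on the same outcome,
monitor siting correlates the two exposures and a single-exposure model
is confounded by the omitted channel. The drivers adjust each channel's
model for the other; the recovery scenarios plant one channel at a time.

## Mediation

Simple (single-mediator) mediation per the product-of-coefficients
scheme: mediator equation M ~ X + covariates, outcome equation
ln(fibrinogen) ~ X + M + covariates, on the same complete-case rows. For
OLS this makes total = direct + indirect an algebraic identity, asserted
to 1e−8 on every fit. The indirect-effect CI is a nonparametric pairs
bootstrap (whole rows, keeping X, M, Y and covariates together) with
bias correction and no acceleration — the convention of the SPSS/SAS
PROCESS macro this class of analyses standardizes on; a percentile option
is one flag away. `z₀` counts ties as half; an empty tail clamps `z₀`
with a warning; bootstrap quantiles are ceiling-indexed order statistics
so a fixed seed reproduces the interval bit for bit. Per-mediator seeds
derive from a hash of the mediator id, so results are invariant to panel
order. Coverage is verified by simulation (500 replicates, B = 999,
nominal 95% within three binomial SEs).

The default B is 10,000; the recovery scenarios and drivers use B = 1,000,
which changes the Monte-Carlo width of the interval endpoints, not the
method. Single-mediator models are a deliberate scope boundary: no joint
multiple-mediator model, no sensitivity analysis for sequential
ignorability.

## Network integration

Bona fide targets require support from ≥ 2 of the six declared prediction
algorithms; disease gene sets keep expert-curated rows for diseases with
≥ 20 genes; enrichment is a one-sided (over-representation) Fisher exact
test per (miRNA, disease) plus a pooled all-disease set, BH-adjusted
across the run, flagged at FDR < 0.1. The default gene universe is the
union of genes in the prediction table; this is configurable and results
are sensitive to it — with a genome-wide universe every test's margins
change. The reported odds ratio is the sample cross-product ratio so the
2×2 table is fully recomputable from the stored counts. Hub genes sit in
≥ 4 disease sets, annotated and sorted by the number of targeting miRNAs;
the pathway overlay reports which supplied miRNAs target each pathway
gene.

Live database clients are out of scope. The packaged tables under
`inst/extdata/` are synthetic (built by `build_network_fixture()`, marked
as such in their filenames) and mirror export structure only; the extdata
README documents the column mapping for real DisGeNET/miRWalk/KEGG
exports. Literal database-version-dependent counts are deliberately not
reproduced.

## Problem sizes and numerical choices

Recovery scenarios run 20 seeded replicates at the emulated cohort sizes
(n = 1630 pooled, 883 discovery, 747 validation) with a two-year daily
exposure series over 5–6 monitors — sizes chosen so each scenario is a
faithful miniature of the design while a full run of the acceptance
protocol completes in minutes on one core. The mediated-flag scenario
uses B = 1,000 resamples per mediator. Tie-breaks, quantile indexing,
reference levels and per-unit coding are all fixed conventions stated
above; degenerate inputs (constant assays, singular designs, empty
panels, subjects with no amplified wells, unamplified reference assays)
raise informative errors or flagged rows rather than silent results.

## What passing tests do and do not show

The generator matches the statistical *structure* the analysis assumes:
log-linear effects, lognormal exposure with seasonal confounding shared
between PM10 and apparent temperature, panel QC artifacts, a planted
mediation truth. It does not emulate joint covariate dependence, spatial
gradients within the region, miRNA–miRNA co-regulation beyond shared
technical factors, repeated measures, or assay-specific amplification
chemistry. Parameter recovery under this generator therefore demonstrates
that the pipeline is internally consistent and unbiased under its own
assumptions — the same claim a simulation study makes — not that any
particular real-world estimate is correct. The fixture-based checks
(QC counts, enrichment contingency tables, pathway coverage) are exact
and generator-independent.
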