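---
title: "Validating clinical prediction models with predvalid: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating clinical prediction models with predvalid: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predvalid)
```

## The problem

A prediction model developed on one cohort does not automatically
perform well on another: case mix, disease severity and treatment
patterns shift. External validation quantifies that transfer. In
practice it is often skipped because every model has to be re-coded by
hand against every new dataset. `predvalid` removes that step: the model
is written once as a declarative specification, the dataset is connected
to it by a mapping configuration, and the validation statistics are
computed by a single engine that is itself heavily tested against
independent oracles.

## Model families and their risk formulas

A `model_spec` carries an ordered list of covariates (continuous with an
optional centering constant, or categorical with an explicit reference
level) and one of four prediction mechanisms. Writing $LP$ for the
linear predictor $\beta_0 + \sum_j \beta_j x_j$ (categorical levels
contribute their coefficient, the reference level 0, continuous values
$\beta (x - \text{center})$):

* **logistic** — $p = 1/(1 + e^{-LP})$, one implicit horizon.
* **conditional annual-risk logistic** — one full coefficient set per
  follow-up year $k = 1..K$; the annual conditional risks
  $r_k = \text{logit}^{-1}(LP_k)$ compose into the cumulative risk
  $1 - \prod_{k \le t}(1 - r_k)$ through year $t$. Allowing fully
  distinct per-year coefficients subsumes the case where effects are
  shared across years.
* **Cox with baseline survival** — the spec tabulates $S_0(t)$ at its
  supported horizons and the event risk is $1 - S_0(t)^{\exp(LP)}$ (no
  intercept; the baseline plays that role). Horizons are matched
  exactly: interpolating a survival curve between tabulated points would
  silently invent information, so an unsupported horizon is an error.
* **profile lookup** — continuous covariates are discretized into
  half-open intervals $[lo, hi)$, the labels form an exact profile key,
  and the spec's table returns the empirical probability for
  (key, horizon). Exact matching is an assumption: real profile-matching
  calculators may tolerate near-matches, but no such rule is published
  for them, and a silent nearest-neighbour fallback would be
  unauditable. An unmatched profile is therefore a hard error naming the
  key.

### Unknown values

Registries rarely deliver complete data. A covariate value can be marked
*unknown* (`NA`): a categorical covariate then contributes the weighted
average $\sum_l w_l \beta_l$ under its spec-declared `unknown_weights`
(the reference level participating with $\beta = 0$), and a continuous
covariate the contribution of its development-cohort mean. Both
mechanisms require the spec to opt in; a model without them cannot score
unknowns, and affected records are excluded instead. This keeps "what
was imputed" an explicit, serialized property of the model rather than a
runtime guess. Lookup models never score unknowns (there is no weighted
average over a lookup table's rows that preserves its empirical
semantics).

## Cohort mapping and missing-data policy

The mapping configuration connects each model covariate to a dataset
column, translates dataset codes to model levels (categorical) or
applies a unit scale factor (continuous), and identifies the outcome's
event/non-event codes. Two policies handle missing values (declared
`missing_codes` plus the empty string — nothing else is guessed):

* `to_unknown` (default): missing becomes unknown where the covariate
  supports it, otherwise the record is excluded;
* `exclude`: any missing value excludes the record.

A record is also always excluded when its outcome is missing. Exclusion
happens **after** code translation, so an undeclared code is a mapping
error (naming column, code and row), never silently treated as missing:
registry codebook drift should surface loudly. The `mapped_cohort`
carries full bookkeeping (`n_input = retained + excluded`, per-variable
missing counts, per-record exclusion reasons), and that conservation
identity is enforced by property tests.

Baseline comparability is assessed per covariate against the spec's
development summary: standardized mean difference with pooled SD for
continuous covariates, per-level standardized differences of proportions
for categorical ones (summarized by the largest absolute per-level
value — chosen over a multivariate Mahalanobis version for
interpretability; each flagged level is directly actionable). Absolute
values above 0.1 are flagged, a conventional threshold for a difference
worth inspecting; no automatic decision is attached to it.

## Calibration

Predicted risks are clipped to $[\varepsilon, 1-\varepsilon]$
($\varepsilon = 10^{-10}$, configurable) before the logit transform;
clipping only ever matters for degenerate engines that emit exactly 0
or 1 (a lookup table can). Two maximum-likelihood logistic fits follow:

* slope $b$ from the unrestricted refit of $y$ on
  $(1, \operatorname{logit} p)$;
* intercept $a$ from the fit of $y$ on an intercept only, with
  $\operatorname{logit} p$ as a fixed offset (slope constrained to 1) —
  the calibration-in-the-large convention standard in the validation
  literature.

Because the literature is split on which intercept to report, the
unrestricted fit's intercept is returned as well
(`intercept_unrestricted`). The fits use Fisher scoring (base R `glm`),
then a few explicit Newton steps so the final score norm is below
$10^{-8}$ — `glm`'s relative-deviance stopping rule alone does not
guarantee an absolute gradient bound at $n = 10^5$. Non-convergence and
single-class outcomes are classed errors, never silent `NA`s.

The grouped calibration table sorts records by predicted risk (stable
sort: ties keep input order, making the grouping reproducible), splits
them into `n_bins` contiguous equal-count groups — sizes
$\lfloor n/B \rfloor$ with the first $n \bmod B$ groups one larger — and
reports per group the mean predicted risk, observed proportion and a
95% Wilson score interval. Wilson was chosen over Wald because extreme
deciles of a well-calibrated rare-outcome model routinely contain 0 or 1
events, where Wald collapses. No smoothed (loess) curve is drawn; the
grouped plot against $y = x$ is the reference display.

## Discrimination

The ROC curve takes every distinct predicted value as a threshold
(predict an event when $p \ge$ threshold), descending, with an $\infty$
sentinel so the curve runs from (0,0) to (1,1). The AUC is computed by
the Mann–Whitney midrank formula — the probability that a random event
outranks a random non-event, ties counted ½ — which equals the
trapezoidal area under that curve exactly; the equality is asserted to
$10^{-12}$ in the test suite against a brute-force pairwise count, and
cross-checked once against an established ROC implementation.

## The synthetic-cohort generator

The generator exists so that every claim above is testable without
patient data. Given a true `model_spec`, it draws covariates i.i.d. from
per-covariate recipes (defaults derived from the spec's development
summaries; lookup-model continuous covariates draw uniformly over their
discretization support so every record matches a profile), computes each
record's model risk $p$, applies a controlled miscalibration
$\operatorname{logit} p' = a_{true} + b_{true} \operatorname{logit} p$,
and draws $y \sim \text{Bernoulli}(p')$. MCAR masking is applied last.
The raw table is emitted with integer dataset codes plus the matching
mapping configuration, so the mapping layer is exercised end to end; a
fixed seed reproduces the files byte for byte.

The four shipped example specs (one per family) use invented
coefficients but realistic shapes for breast-cancer prognosis models:
a six-covariate logistic model at ~24% event prevalence, a five-period
conditional recurrence model at ~2%, a Cox model with 5-/10-year
baseline survival at ~13% five-year mortality, and an 18-profile lookup
model — spanning the prevalence range (roughly 2–25%) and missingness
(0–24% per variable) typical of registry validation cohorts.

A survival variant draws event times
$T \sim \text{Exponential}(\lambda_0 e^{LP})$ with uniform censoring and
drops pre-horizon censored records (with a count), because the
validation core requires a fully observed binary status at the horizon —
partial follow-up is out of scope, and multiple imputation of outcomes
is deliberately not offered. Note the exponential law is its own
data-generating process: such a cohort is not exactly calibrated for a
Cox spec with a non-exponential baseline table.

What the generator does **not** emulate: correlated covariates (draws
are independent), informative missingness, measurement error, or real
registry codebooks. Passing tests on synthetic cohorts therefore
demonstrate the correctness of the computation, not the clinical
performance of any model on real data.

## Problem sizes and numerical choices

The test suite works at the smallest sizes that make each claim sharp:
oracle equivalences at $n \le 500$ (agreement to $10^{-8}$ is a
deterministic property, not a sampling one), parameter recovery at
$n = 10^5$ with three seeds per scenario and 3-standard-error bounds
from the fits' asymptotic variances, and the two-pipeline agreement
re-enactment on 20 cohorts of $n = 2000$ across all four families,
requiring $|\Delta a|, |\Delta b| \le 0.03$ and AUCs identical to two
decimals between the engine and a deliberately naive scalar
re-implementation. Ties in predicted risks are handled identically in
both routes by construction of the statistics (midranks; stable sort),
so the agreement margin is consumed by nothing — both routes agree to
numerical precision, comfortably inside the envelope.

Degenerate inputs are contracts, not corner cases: single-class
outcomes, fewer records than bins, unsupported horizons, unmatched
profiles, unknown values without unknown support, and undeclared codes
each raise a distinct classed error (`pv_*_error`) that the CLI maps to
exit code 2 (64 for usage errors).

## Known limitations

* No multiple imputation; missing data are either scored as unknown by
  the model's own declared mechanism or excluded.
* No censoring-aware validation (fixed-horizon binary outcomes only).
* No Brier score, Hosmer–Lemeshow, reclassification or decision-curve
  measures; no confidence intervals around $a$, $b$ or the AUC.
* Only identity/centering covariate transforms; splines and fractional
  polynomials are reserved in the schema (`transform`) but not
  implemented.
* Exact-match lookup and exact-horizon Cox evaluation, as discussed
  above.
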