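---
title: "Methods behind mirrorscreen: triage rules, ordinal psychometrics, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind mirrorscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirrorscreen)
```

This vignette documents the models, defaults and numerical choices behind the
package, in the spirit of a methods appendix: what is computed, under which
assumptions, and where the design was genuinely open.

## The triage model

MIRROR's algorithm is a deterministic decision table over three banded
inputs. The PTSD scale (sum of 4 items, range 4–20) and the functioning
rating (1–10) are banded low/moderate/high; resilience (sum of 3 items,
3–15) low/high; the time phase is one of under 1 week, 1–4 weeks, over
4 weeks, or recurring. Two conventions needed fixing where the instrument's
verbal description is silent:

* **Interval boundaries.** "Between 1 and 4 weeks" is read as the closed
  interval [1, 4] and "less than 1 week" as [0, 1); a recurring event
  dominates any week count. Scale cutoffs are closed upper bounds of the
  lower band: a PTSD total exactly at the low/moderate cutoff is *low*. Both
  choices are deterministic, documented, and configurable.
* **Cutoffs and the outcome grid.** The deployed instrument's exact numeric
  cutoffs and 36-cell outcome table are not part of the published text. The
  defaults are scale-range terciles — PTSD low ≤ 9, moderate 10–14, high
  ≥ 15; functioning low ≤ 4, moderate 5–6, high ≥ 7; resilience low ≤ 9 —
  which straddle the reported sample means (PTSD ≈ 14.9, functioning ≈ 5.0,
  resilience ≈ 10.1), combined with a decision table built from the published
  verbal rules: low functioning always refers to care, whatever the
  complaints level; complaints (moderate or high) with moderate functioning
  are normalized while the event is recent but become red past 4 weeks or
  when the event recurs; green requires low complaints with at least moderate
  functioning, or high functioning with at most moderate complaints. The
  "and/or" in the green rule is resolved conservatively: green is never
  granted with low functioning. Both cutoffs and table are shipped as JSON
  (`inst/extdata/triage_config.json`) so the deployed values can be dropped
  in; `triage_config()` validates totality (all 36 cells exactly once),
  strictly increasing cutoffs, and color vocabulary before any
  classification.

The enumerated default table satisfies three properties that the test suite
checks by brute force: color severity is non-decreasing in the complaints
band and non-increasing in the functioning band at fixed phase;
orange cannot persist past 4 weeks when complaints meet low-to-moderate
functioning; and the resilience band never alters the color, only the advice
(support encouragement appears if and only if resilience is low).

## Reference-instrument scoring

PCL-5, DASS-21, RES and MHC-SF are scored exactly as their manuals and the
validation design prescribe: plain sums (with DASS-21 sums doubled to the
full-scale metric), the DSM-5 provisional-diagnosis rule (item ≥ 2 endorsed;
≥ 1 B, ≥ 1 C, ≥ 2 D, ≥ 2 E), and fixed — not recomputed — tertile cutpoints
for RES (≤ 17 / 18–24 / ≥ 25) and MHC-SF (≤ 23 / 24–47 / ≥ 48). Two details
are worth noting. First, the printed DASS band limits leave one-point integer
gaps between adjacent bands; the package closes them following the standard
manual banding (normal ≤ 9/≤ 7/≤ 14, mild to 13/9/18, moderate to 20/14/25,
severe to 27/19/33, extremely severe above) so that every attainable doubled
score receives exactly one band, with normal + mild forming the subclinical
group. Second, the PCL-5 cluster assignment (items 1–5 B, 6–7 C, 8–14 D,
15–20 E) follows the standard published instrument ordering, as only the
cluster sizes are given in the validation design.

## Ordinal psychometrics

The evaluation treats the 5-category MIRROR items as ordinal indicators of
underlying normal variables, each divided by 4 estimated thresholds. The
10-category functioning rating is included in the same polychoric treatment
(with 9 thresholds) rather than as a continuous variable: with 10 categories
the polychoric and Pearson coefficients are close, and one uniform code path
keeps the correlation matrix internally consistent.

**Polychoric correlations** use the two-step estimator: thresholds fixed at
normal quantiles of the marginal cumulative proportions, then a
one-dimensional maximization of the multinomial likelihood of the observed
contingency table over the latent correlation (golden-section search on
(−0.999, 0.999), tolerance 1e−6, cell probabilities floored at 1e−12). The
bivariate normal CDF is evaluated by 48-node Gauss–Legendre quadrature of the
derivative-in-correlation identity, accurate to ~1e−10 against direct
numerical integration. Zero-variance variables are rejected by name, and a
polychoric matrix that is not positive semi-definite is smoothed by flooring
its eigenvalues at 1e−4 and rescaling to unit diagonal.

**Factor analysis.** Extraction is unweighted least squares (minres):
uniquenesses are optimized by L-BFGS-B (bounds [0.005, 0.995], started at
1 − squared multiple correlations), with the rank-m loadings obtained from
the eigendecomposition of the reduced matrix. Oblique geomin rotation
(ε = 0.01) uses the gradient-projection algorithm from 10 deterministic
starts (identity plus 9 pseudo-random oblique matrices from a fixed internal
seed, so results do not depend on the caller's RNG state); the lowest
criterion wins, factors are ordered by explained variance and signed so each
factor's dominant loading is positive. CFA fits the congeneric model
(one factor per item, unit latent variances, correlated factors,
unit-diagonal implied matrix) by BFGS on the loadings and tanh-parameterized
factor correlations, with barrier penalties keeping uniquenesses above 0.001
and the factor-correlation matrix positive definite.

**Fit statistics.** The published analyses used a weighted least squares
estimator for ordinal data (WLSMV) in dedicated SEM software; replicating its
chi-square and difference testing bit-exactly is out of scope. The package
instead evaluates the normal-theory maximum-likelihood discrepancy
`F = log|Σ| − log|S| + tr(SΣ⁻¹) − p` at the least-squares solution and
reports `χ² = (N − 1)F`, with the independence model on the same matrix as
baseline. CFI and TLI follow their standard formulas and are clamped to
[0, 1]; RMSEA is 0 whenever χ² ≤ df. Degrees of freedom follow the standard
covariance-structure bookkeeping, which reproduces the published dfs for
both the EFA models (13 and 7 for the 2- and 3-factor solutions of 8 items)
and the CFA models (19 and 17). This approximation is expected to reproduce
structure — which items load where, eigenvalue ordering, the Kaiser count,
and the relative fit of nested models — not the published decimals, and the
tests assert exactly those structural claims. Nested models are compared by
Δχ², Δdf and ΔCFI with the practical rule that the simpler model is retained
unless its CFI is worse by 0.01 or more.

**Group comparisons.** The classic and Welch one-way F, Games–Howell post hoc
comparisons (unpooled variances, Welch–Satterthwaite df, studentized-range
p-values over all k groups), the chi-square test of independence and the
two-sample t tests all depend only on group summary statistics, so the
functions accept either raw vectors or printed means/SDs/ns — printed summary
tables are first-class inputs. Raw-data paths are cross-checked in the test
suite against `aov`, `oneway.test` and `t.test`. Eta-squared
(SSB/(SSB+SSW)) is the reported effect size; no multiple-testing correction
is applied beyond the family-wise control built into the studentized-range
distribution, matching the evaluation design.

## The synthetic cohort

The study's respondent-level data are not deposited, so the package carries a
seeded generator whose defaults encode the study conditions; it is the
fixture for every end-to-end test.

* **Latent structure.** Two standard-normal latents — PTSD complaints and
  psychosocial resources — with correlation −0.45. No factor correlation is
  published for the 2-factor solution; −0.45 is a free parameter chosen so
  the scale-level validity correlations land near their published values, and
  it is a tunable, not a claim.
* **MIRROR items.** Each item is a thresholded linear combination
  `loading × latent + √(1 − loading²) × noise`. Loadings default to 0.6 for
  the PTSD and resilience items. The functioning rating loads 0.4 on
  resources with a −0.25 cross-loading on complaints: the published geomin
  solution loads functioning at only 0.354 on resources with a −0.153
  cross-loading, and a pure 0.6 resources placement would both overstate
  functioning's coupling to the resources-side reference measures and
  understate its coupling to the complaint measures. Item thresholds are set
  to the normal quantiles of the published item-category margins (Tables of
  response-category frequencies), so the simulated margins — and hence scale
  means near PTSD ≈ 14.9 and functioning ≈ 5.0 — match the study population
  in expectation.
* **Reference batteries.** Each instrument gets an instrument-level factor
  `T = w₁·complaints + w₂·resources + u·ε` with weights calibrated once so
  the simulated scale-level Pearson correlations approximate the published
  validity matrix (PCL-5 × MIRROR-PTSD ≈ 0.66, RES × MIRROR-resilience
  ≈ 0.61, DASS-21 × functioning ≈ −0.45): w = (0.70, −0.36) for PCL-5,
  (0.36, −0.60) for DASS-21, (0.04, 0.87) for RES, (0.04, 0.86) for MHC-SF.
  Items load 0.75 on their instrument factor with instrument-specific
  threshold sets. This is scale-level calibration; no attempt is made to
  match the published item-level psychometrics of PCL-5 or DASS-21, and with
  a single resources factor the correlations of RES/MHC-SF with the
  functioning item run somewhat higher than published while PCL-5/DASS-21
  with functioning are matched.
* **Event context.** Event type, relation and time phase are i.i.d.
  categorical draws with the validation sample's published frequencies
  (e.g. 36.3% under 1 week, 9.7% recurring); weeks are uniform within the
  drawn phase band, as only phase frequencies are published. The relation
  vocabulary treats work-relatedness as a fifth relation category with its
  published 11.6% share folded out of the other categories, although the
  instrument records it as a separate cross-cutting flag.
* **Determinism.** The same configuration and seed yield a byte-identical
  cohort; disjoint seeds share no state.

What the generator does *not* emulate: longitudinal trajectories (repeat
records are flagged and excluded, not modelled), demographic covariates,
differential missingness, careless-responding patterns, and any dependence of
the event context on symptom severity. Passing tests on synthetic cohorts
therefore demonstrate that the pipeline recovers planted structure under the
assumed measurement model — not that the instrument behaves identically on
real respondents.

## Cohort screening

`read_cohort` applies the evaluation design's exclusion rules in a fixed
order — proxy use, repeated measurement, incomplete record (missing MIRROR
items/context or a partially completed battery), externally flagged unusual
answering pattern, and contract violations (range or vocabulary) — counting
each rejected row under the first matching reason and logging every
rejection, so that accepted + rejected always equals the input count. The
"unusual answering pattern" judgment is a manual review step in the original
design; it enters the package only as an explicit flag column, never as an
inferred heuristic.

## Problem sizes and runtime choices

The reference cohort size for distribution-level checks is n = 5000 (scale
correlations, factor recovery, classification-ordering checks), with n = 1112
— the study's retained sample size — used for the repeated-seed fit-index
ordering checks and n = 10000 for simple frequency checks. These sizes keep
sampling noise well inside the asserted tolerances while the full test suite
runs in well under a minute. The 20-seed CFA ordering check uses study-size
cohorts deliberately: fit-index ordering should hold at realistic sample
sizes, not only asymptotically.

## Known limitations

* Fit indices are normal-theory ML approximations on polychoric input, not
  WLSMV; published chi-squares and RMSEAs are reproduced in ordering and
  rough magnitude only.
* The default triage cutoffs and decision table are provisional
  reconstructions from verbal rules; deployments must supply the instrument's
  own configuration.
* The Games–Howell p-values rely on the asymptotic studentized-range
  distribution; no bootstrap is offered for polychoric-based statistics.
* English paraphrases of the items are treated as canonical labels; the
  Dutch originals are not reproduced, and no claim of translation fidelity is
  made.
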