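---
title: "Estimating minimally important differences for paired clinical measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating minimally important differences for paired clinical measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midkit)
```

## The problem

A clinical trial or monitoring programme that uses a continuous measurement
as an end-point needs to know how large a change is *meaningful* — the
minimally important difference (MID). midkit estimates MIDs for metrics
measured at two timepoints per patient (here, cardiac-MRI right-ventricular
metrics in pulmonary arterial hypertension: ejection fraction RVEF in %, and
the volumes RVEDV/RVESV/RVSV in mL), benchmarked to external *anchors* of
how the patient feels (the emPHasis-10 quality-of-life score, E-10),
functions (incremental shuttle walk test distance, ISWT) or survives (1-year
vital status after the follow-up measurement).

Change is always computed as follow-up minus baseline; clinical
direction is resolved through each metric's `direction_of_benefit`
(+1 for RVEF, −1 for the volumes), never by re-subtracting in the other
order. Both an absolute change and a relative change (absolute change
divided by baseline, undefined and flagged when the baseline is zero) are
analysed.

## Anchor classification and screening

A change-threshold anchor classifies each patient with complete anchor
pairs: with signed anchor change $d$ (follow-up − baseline), improvement
sign $s$ and threshold $t$,

* improved if $d\,s \ge t$,
* worsened if $d\,s \le -t$,
* stable otherwise.

The thresholds are the anchors' own established MIDs: 6 points for the E-10
(lower is better, $s = -1$) and 47.5 m for the ISWT ($s = +1$). A change
exactly at the threshold counts as changed: the threshold is defined as the
minimal *important* change of the instrument, so a change that reaches it is
important. Patients missing either anchor timepoint are excluded pairwise
from that anchor's analysis and counted; the three labels always partition
the analysable patients. The survival anchor simply contrasts survivors with
non-survivors of the year following the follow-up scan, so it supports
worsening-direction MIDs only; improvement cells are reported as
`not_defined` rather than silently omitted.

A metric–anchor pair enters MID estimation only if the changes are at least
weakly correlated: Pearson $|r| > 0.20$ on pairwise-complete changes. The
absolute value is deliberate — an anchor whose score falls with improvement
correlates *negatively* with a metric that rises with improvement, and the
magnitude carries the responsiveness information. `normalize_to_six_units()`
(z-scores rescaled to a 6-unit span, the E-10's own MID scale) is provided
for reporting parity, but because Pearson correlation is invariant to affine
maps the screen is computed on raw changes; the two cannot disagree, and the
test suite asserts as much. The survival anchor has no change score of its
own to correlate, so a metric is admitted to the mortality-anchored analysis
when it passes the screen against at least one change-threshold anchor —
the same admission logic that keeps a metric in play when it is responsive
to one anchor but marginal against another. No p-values are attached to the
screen; the decision is on magnitude only.

## The four estimators

Let $x_i$ be a patient's change score on the chosen scale.

**0.5 sd** (distribution-based): half the sample standard deviation
(n − 1 denominator throughout the package) of the change scores *within the
changed group* — the improved group for improvement MIDs, the worsened
group for worsening MIDs.

**Minimal detectable change** (distribution-based): from the standard error
of measurement,
$$\mathrm{sem} = \mathrm{sd}(x)\sqrt{1 - \mathrm{ICC}}, \qquad
  \mathrm{MDC} = 1.96\,\sqrt{2}\,\mathrm{sem},$$
the smallest change distinguishable from test–retest measurement error at
95% confidence. The sd here is taken over the change scores of *all*
patients contributing to the given anchor analysis (not a changed subgroup):
subgrouping is tied to the 0.5 sd method only, and the SEM describes the
instrument, not a patient stratum. The n counts on every output row make
this choice auditable.

**Change difference** (anchor-based): mean change in the changed group minus
mean change in the stable group (non-survivors minus survivors for the
survival anchor), adjusting the changed group's drift by that of patients
the anchor calls unchanged.

**Regression** (anchor-based): an identity-link least-squares fit of the
change score on dummy indicators of anchor status. A formulation with
indicators for all three groups *plus* an intercept is rank-deficient, so
the model is fit with the stable (survivor) group as the reference level:
the intercept is then the stable group's mean change and the improvement /
worsening coefficients are the incremental change relative to stable. Under
this coding the coefficients coincide algebraically with the change
difference; the package keeps both routes (group means vs `lm()`) and the
test suite asserts their agreement to 1e−8 on random data, so the regression
acts as an independent cross-check rather than a hidden duplicate.

**SEM floor.** An anchor-based MID smaller in magnitude than the SEM is
indistinguishable from measurement error, so the SEM is then used as the
MID (`floored = TRUE` in the output, sign preserved). The inequality is
strict — an estimate exactly equal to the SEM stands — and the rule never
touches distribution-based estimates.

**Signs.** Improvement MIDs are reported in the beneficial direction of the
metric (positive for RVEF, negative for volumes) and worsening MIDs in the
opposite direction. Distribution-based magnitudes are signed by this
convention; anchor-based estimates keep their empirical sign, which matches
the convention whenever the observed effect runs the expected way.

## Aggregation and reporting

`estimate_all()` emits one long-format row per metric × anchor × method ×
direction × scale with value, SEM, floor flag, group sizes, screen r and a
status (`ok`, `screened_out`, `not_defined`, `error`); failures in one cell
never abort the others. `summarize_mids()` then reports, per metric ×
direction × scale, the *mean and range of method-level means*: each method
is first averaged over its anchors (simple, unweighted — group sizes differ
between anchors, but the anchors are conceptually equal benchmarks, and the
per-method means remain available so an n-weighted reading can be
reconstructed), and the mean and min–max range are taken across methods.
`heatmap_table()` exposes exactly those method × metric means, in the fixed
row order half_sd, mdc, change_difference, glm_regression with average
margins, as a plain table. Relative-scale summaries are expressed as
percentages of baseline.

## The synthetic cohort generator

No patient-level registry data can be shipped, so `generate_cohort()` draws
cohorts with the statistical structure the analysis assumes, and
`paper_calibrated_config()` fixes the study conditions: 254 patients, an
improved/stable/worsened mixture of 0.35/0.47/0.18, anchor attrition
leaving about 118 E-10 and 146 ISWT pairs, and a 1-year death fraction near
10% (class-specific death probabilities 0.02/0.08/0.30).

Per patient:

1. a latent status class is drawn from the mixture;
2. each anchor's change score is drawn from a Gaussian **truncated to the
   class's threshold region** (parent means: E-10 −16/0/+13 points,
   sd 8; ISWT +160/−1/−101 m, sd 90). The study's groups are *defined* by
   the observed anchor change, so the class-conditional change distribution
   is supported on the class region by construction; a consequence worth
   stating plainly is that anchor-defined groups coincide exactly with the
   generative classes, making the planted class contrasts the exact
   estimand of the anchor-based estimators — recovery tests then measure
   estimator error, not label noise;
3. each metric's true change is Gaussian around its class mean, coupled to
   the anchors through a Gaussian copula. The copula coefficients are not
   set directly: `calibrate_correlations()` solves for them in closed form
   so that the *population Pearson correlation between observed changes*
   equals the configured target, accounting for the between-class mean
   structure, the truncated anchor margins (via 1-D quadrature of the
   copula covariance) and the metric's measurement-error variance.
   Infeasible targets fail validation before any sampling;
4. observed baseline and follow-up add i.i.d. Gaussian measurement error
   with variance $(1-\mathrm{ICC})\,\sigma_b^2$, so test–retest replicates
   of the metric achieve the configured ICC and the observed baseline sd
   equals the configured one;
5. survival is Bernoulli with the class-specific death probability.

Calibrated values and their provenance:

| quantity | value | basis |
|---|---|---|
| metric baselines | RVEF 34±11 %, RVEDV 207±71 mL, RVESV 141±62 mL, RVSV 66±20 mL | published cohort moments |
| metric class mean changes | RVEF +10.5/+7/+5; RVEDV −22.5/−5.5/−3; RVESV −36/−19/−13; RVSV +4/+4/+4 | average of the two anchor-stratified published tables; RVSV flat (the planted screen-out metric) |
| metric change sds | 10 / 40 / 35 / 20 | plausible change-score spread for these instruments (≈ published timepoint sds with a baseline–follow-up correlation of 0.8–0.9) |
| ICCs | 0.94 / 0.98 / 0.97 / 0.90 | typical scan–rescan reliabilities of automated CMR segmentation; overridable per metric |
| correlation targets | RVEF −0.25/+0.20; RVEDV +0.28/−0.28; RVESV +0.32/−0.34; RVSV −0.10/+0.10 (E-10/ISWT) | published screen correlations; signs follow direction_of_benefit × improvement_sign (one published sign is inconsistent with that structure and is taken as a typographical slip, magnitude kept) |

A heavy-tailed variant (`tails = "t"`) swaps the metric's idiosyncratic
Gaussian component for a scaled Student-t and is off by default. What the
generator does **not** emulate: class-dependent baselines (worsened patients
tend to start better on the anchor), informative anchor missingness,
support constraints (a simulated walk distance can be negative),
metric–metric correlations beyond those induced via shared anchors, and
more than two timepoints. Passing tests therefore certify the estimators
and pipeline plumbing under the assumed structure, not robustness to those
real-data features. One published oddity is kept verbatim rather than
silently repaired: the worsened-group ISWT baseline sd of 16 m is
implausibly small next to every other cell; it does not enter the generator
(which uses a common anchor baseline sd), but is flagged here for anyone
calibrating baselines per class.

## Numerical and design choices

* **Boundary:** |anchor change| equal to the threshold counts as changed
  (≥ / ≤). The alternative (strict) reading is defensible; this one follows
  the anchors' own MID definitions.
* **SEM floor:** strict `<`, so an estimate exactly at the SEM is unfloored.
* **sd denominators:** sample (n − 1) everywhere.
* **Smallness:** estimators refuse groups with fewer than 2 patients, and
  the regression refuses any missing class; `estimate_all()` converts such
  refusals into `error` rows per cell.
* **Degenerate inputs:** zero-variance series make the screen and the
  six-unit rescale fail loudly; zero baselines flag the relative scale as
  undefined for that patient.
* **Determinism:** one seed drives the whole generation in a fixed draw
  order; identical seed and config reproduce cohort, MID table and summary
  CSVs byte for byte.
* **Config files:** metric/anchor definitions are plain-text YAML.

Problem sizes used by the test suite, chosen to make each check sharp at
desk scale: correlation and ICC calibration are verified on single cohorts
of 20 000 and 5 000 (Monte-Carlo error well inside the asserted ±0.03 and
±0.02); recovery of planted change-difference MIDs uses 200 replicates at
the calibrated n = 254 and is asserted within 3 Monte-Carlo standard
errors; the screen's operating characteristics use 1 000 replicates at the
calibrated attrition (pass rates ≥ 90% at planted r = 0.30 under the
either-anchor admission rule, ≤ 10% at r = 0); invariants (label
partitions, floor dominance, affine invariance, estimator identity) run on
100–1 000 randomised cases under fixed seeds.

## Limitations

The two anchor-based methods coincide under identity-link least squares, so
the four methods contribute three genuinely distinct estimators; the
regression route would differ only with covariates or a non-identity link,
neither of which is in scope. No confidence intervals are attached to MIDs.
The mortality anchor supports worsening only, and its contrast (survivor
mixture vs non-survivor mixture of latent classes) is a different estimand
from the threshold anchors' class contrast — the package reports all
anchors separately so the distinction stays visible. MIDs estimated from a
single-centre-style calibration should be treated as exploratory for any
other population.
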