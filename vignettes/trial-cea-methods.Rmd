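---
title: "Methods: trial-based cost-effectiveness analysis with trialcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-effectiveness analysis with trialcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

trialcea implements a trial-based health-economic evaluation for a two-arm
randomised trial of internet-delivered cognitive behaviour therapy (ICBT)
against an active online control, with body dysmorphic disorder as the
motivating indication. This vignette is the package's own account of the
statistical and economic machinery: the models, the costing rules, the
choices that were genuinely open, and what the synthetic-data generator can
and cannot tell you about real trials.

## The evaluation problem

A trial measures, at pre-treatment, post-treatment (3 months) and follow-up
(6 months):

* **remission** — no longer meeting diagnostic criteria at a blinded
  structured interview (undefined at pre-treatment);
* **EQ-5D utility** — a five-domain health-status profile mapped to a
  utility index on the quality-adjusted life-year (QALY) scale, 1 being
  full health;
* **resource use** — a TIC-P style questionnaire over a 4-week recall
  window: health-care visits, medication, sick-leave days, domestic work
  cutback hours, and unemployment status.

The economic question is whether the intervention's extra benefit is worth
its extra cost. The package answers it with incremental
cost-effectiveness ratios (ICERs), the net-benefit framework, and
bootstrap acceptability curves, under three nested costing perspectives.

## Costing model

All costing rules live in `compute_costs()` and `tariff_table()`:

| rule | default | unit |
|---|---|---|
| visit/medication unit costs | Swedish-tariff style CSV (e.g. specialist 2600 SEK) | SEK/unit |
| sick leave (human capital) | 8 h/day x 188 SEK/h | SEK/day |
| domestic cutback | 14 EUR/h x 9.10 SEK/EUR | SEK/h |
| unemployment | 24 000 SEK per 12-week period | SEK/period |
| recall extrapolation | x 12/4 (4-week recall to 12-week period) | — |
| currency | 6.861 SEK per USD (2014 purchasing power parity) | — |
| treatment provision | \$946 intervention / \$461 control, booked once at post-treatment | USD |

Categories are additive and nested: **clinic** counts treatment provision
only; **health care** adds other health-care visits and medication;
**societal** adds sick leave, domestic cutback and unemployment. A fourth
label, `societal_excl_unemployment`, supports the sensitivity analysis.

Three choices here were open and are worth recording:

* **Hours per sick day.** Only an hourly wage is given for the
  human-capital approach; the package uses a standard 8-hour working day,
  configurable in `tariff_table()`.
* **EUR to SEK.** Domestic work is priced in EUR; the conversion to SEK is
  not pinned down by the wage tariffs, so the 2014 average of 9.10 is the
  default and is configurable.
* **Unemployment is not recall-extrapolated.** 24 000 SEK is 80% of a mean
  monthly gross salary scaled to the assessment period — already a
  per-period amount. Extrapolating it by 12/4 would triple it and
  contradict its dollar value of \$3498 at the 6.861 rate.
* **Clinic costs carry forward.** Treatment provision is a one-off cost of
  the 12-week treatment period, booked at post-treatment. The
  clinic-perspective incremental cost at follow-up therefore reuses the
  post-treatment contrast rather than a (zero) follow-up flow; the broader
  perspectives are left alone, since their follow-up contrasts are
  questionnaire-driven.

Money is kept at full precision internally and rounded to whole dollars
only in written reports. Missing questionnaire items make the
questionnaire-derived categories of that record missing; the administrative
treatment-provision cost is always defined.

## Outcome and inference model

For a numeric outcome $y_{it}$ (EQ-5D index or a perspective cost),
`fit_outcome_model()` fits by maximum likelihood

$$ y_{it} = \beta_0 + \beta_g g_i + \beta_t \mathbb{1}[t] +
  \gamma_t\, g_i \mathbb{1}[t] + b_i + \varepsilon_{it}, \qquad
  b_i \sim N(0, \tau^2),\ \varepsilon_{it} \sim N(0, \sigma^2) $$

with time categorical (pre-treatment as reference) and a participant
random intercept. The interaction coefficient $\gamma_t$ is exactly the
difference-in-differences (DiD): the intervention arm's change from
baseline minus the control arm's. On balanced complete data the
least-squares means equal raw cell means and $\gamma_t$ equals four-cell
arithmetic; the tests hold this to $10^{-6}$ as an oracle. Missing
outcomes are handled by the likelihood (no imputation), valid under
missing-at-random (MAR) dropout. Non-convergence is flagged on the
returned object, never silenced.

Costs are modelled on the raw dollar scale — incremental *arithmetic mean*
costs are what a budget holder pays, so no log transform is applied
despite the skewness; the bootstrap, not normal theory, carries the
inferential weight.

The group-by-time interaction is tested with a 2-degree-of-freedom ML
likelihood-ratio test. At the default trial size (47 per arm) its
simulated type-I error is close to, and slightly above, the nominal 5%
(approximately 6% in the package's own null simulation), which is the
expected small-sample behaviour of an ML likelihood-ratio test.

**Effect sizes.** Cohen's $d$ divides a model contrast by a standard
deviation. "The residual standard deviation of the random-effects model"
is ambiguous between $\sigma$ and $\sqrt{\tau^2+\sigma^2}$; the package
defaults to $\sigma$ (`sigma = "residual"`) and offers the total-SD
convention as an option. Both are reported per timepoint, within-group
(one arm's change) and between-group (the DiD).

**Remission.** The headline cost-effectiveness scale is the difference in
arm remission *proportions* (e.g. 0.32 − 0.02 = 0.30), which is what an
ICER "per case in remission" divides by, so that is the estimator used in
the bootstrap. Odds ratios are reported from a mixed-effects logistic
model (`remission ~ arm * timepoint + (1 | participant)`); when that fit
fails or is separation-prone (a near-empty control cell is common at 2%
remission), the estimator falls back to per-timepoint 2x2 odds ratios
with the Haldane–Anscombe correction and says so in its `method` column.
Conditional (mixed-model) and marginal (2x2) odds ratios are different
estimands; the package exposes both and never mixes them.

## Bootstrap, ICERs and acceptability curves

`bootstrap_cea()` resamples **participants** (all their timepoints) with
replacement, stratified by arm with arm sizes preserved — the standard
choice for trial-based CEA, since the participant is the independent
sampling unit and the design fixes the arm sizes. Per replicate the same
mixed models are refitted (`method = "mixed"`); a fast mode
(`method = "cellmeans"`) substitutes observed cell-mean DiD arithmetic,
an approximation that coincides with the mixed model exactly on complete
balanced resamples and is used where thousands of refits would be wasted
on quadrant proportions. Replicates whose refit fails are redrawn and
counted.

From the replicate cloud of incremental cost and effect pairs
$(\Delta C_b, \Delta E_b)$:

* `icer()` is $\Delta C / \Delta E$, reported as `NA` (with a warning)
  when $\Delta E = 0$ rather than a silent infinity;
* `net_benefit()` is $\lambda \Delta E - \Delta C$;
* `ceac()` reports, per willingness-to-pay $\lambda$, the fraction of
  replicates with strictly positive net benefit. A tie at exactly zero
  counts as *not* cost-effective — a measure-zero event for continuous
  outcomes, made deterministic for reproducibility;
* `quadrant_proportions()` classifies replicates by sign into the four
  cost-effectiveness-plane quadrants, zeroes assigned to the positive
  side, so the four proportions always sum to one.

The default willingness-to-pay grid is \$0–\$60 000 in \$1000 steps,
covering the thresholds usually cited for a QALY and for a case in
remission.

## The synthetic trial generator

No participant-level data ship with the package; `simulate_trial()`
generates trials with the statistical structure the analysis assumes, so
every downstream stage is testable end to end.

* **Arms and visits:** 47 participants per arm by default, three
  timepoints.
* **Remission:** Bernoulli with arm x timepoint probabilities (defaults
  2%/32% at post, 9%/40% at follow-up), made persistent by a shared
  per-participant latent uniform, so remitters at post remain remitters at
  follow-up when probabilities are non-decreasing.
* **EQ-5D:** random-intercept Gaussian around arm x timepoint means
  (defaults 0.75/0.67/0.67 control, 0.71/0.73/0.80 intervention; intercept
  SD 0.15, residual SD 0.17), clipped to the value-set range with a
  *mean-preserving location adjustment*: the latent cell location is
  solved (closed-form clipped-normal mean, `uniroot`) so the post-clipping
  mean equals the configured mean. Without this, cells near the upper
  bound would be biased low by up to ~0.02 and parameter-recovery checks
  would conflate clipping bias with estimator bias.
* **Costs:** negative-binomial counts for visits, medication and
  sick-leave days and gamma domestic hours, with small size/shape
  parameters (0.25–0.4) giving the heavy right skew and zero inflation
  typical of resource-use questionnaires; unemployment is a persistent
  Bernoulli flag (shared latent uniform). Default item rates are
  *back-solved* from published arm x timepoint cost means under the
  default tariff, so the expected societal and health-care means match
  the published descriptive table by construction. The control arm's
  unemployment probabilities are calibrated to published per-timepoint
  unemployment cost means (\$893/\$228/\$1220); the intervention arm's
  are unstated anywhere and set to a flat 20%.
* **Dropout:** `apply_missingness()` removes values per instrument
  (diagnostic interview, EQ-5D, TIC-P) at the published per-arm completion
  rates (e.g. 40/47 = 85% diagnostic interviews at follow-up in the ICBT
  arm), with completion logit-linear in the observed baseline utility
  (slope 2 by default) and the intercept solved numerically against the
  empirical baseline distribution so the marginal rate is hit. This is a
  genuine MAR mechanism: missingness depends on observed data only, which
  the test suite verifies by conditional-independence regression.

What the generator does *not* emulate: within-participant correlation of
cost items over time beyond unemployment persistence, item-level
correlation between cost categories, EQ-5D measured as domain profiles
(indices are generated directly; `eq5d_index()` handles profile data when
supplied), or informative (MNAR) dropout. Passing tests therefore
demonstrate correctness of the estimators under the stated data-generating
assumptions, not robustness to every failure mode of real trial data. A
heteroscedastic residual option for robustness experiments can be obtained
by fitting to transformed outcomes; it is deliberately not a generator
default.

## Sensitivity analyses

* **Complete cases** (`complete_case_filter()`): completeness is defined
  *per analysis* — the columns that analysis uses, at the timepoints it
  uses — rather than one global listwise deletion, because completion
  differs by instrument. Remission is undefined at pre-treatment by
  construction and is never consulted there. With no missing data the
  complete-case and likelihood-based runs coincide exactly (tested).
* **Excluding unemployment** (`run_excluding_unemployment()`):
  unemployment costs are large fixed amounts a few participants can
  dominate, so the societal bootstrap is re-run on
  `societal_excl_unemployment` and the quadrant proportions are reported
  side by side. Clinic and health-care results are untouched by
  construction.

## Numerical choices and degenerate inputs

* ML estimation throughout (`REML = FALSE`), so likelihood-ratio
  comparisons of nested mean structures are valid; lme4's optimizer with a
  raised evaluation cap.
* A cost column constant within every cell (the clinic perspective when
  only treatment provision contributes) makes the mixed model degenerate;
  the package detects this and uses exact cell-mean arithmetic instead of
  a non-converging fit.
* Zero incremental effect: ICER undefined, returned as `NA` with a
  warning. Zero net benefit: not cost-effective. Zeroes on the
  cost-effectiveness plane: positive side.
* Seeds: every stochastic stage (generation, dropout, resampling) takes
  one; `run_cea_pipeline()` derives per-stage seeds by small fixed offsets
  from its single seed so the full run is byte-reproducible.
* The toy EQ-5D value set is floored at 0 to match the stated 0-to-1
  index range; real national value sets allowing states worse than dead
  are accepted with a negative floor.

## Problem sizes used by the test suite

The packaged checks run at sizes chosen to separate signal from
Monte-Carlo noise while staying desk-scale: law-of-large-numbers checks
at 10 000 participants per arm (tolerance 0.01–0.02), type-I error with
1000 simulated null trials at the default 47 per arm, parameter recovery
with 500 replications of 1000 per arm in the fast DiD mode, bias
comparisons at 500 per arm over 30 replications, and bootstrap property
checks at B = 1000.

## Known limitations

* The published odds ratios, CEAC percentages and Cohen's d values from
  the motivating trial depend on its raw participant data, which are not
  public; the package reproduces the *arithmetic* of the published worked
  examples exactly and the *qualitative geometry* (northeast-quadrant
  majority, rising acceptability curves) on calibrated synthetic trials,
  but not those participant-level statistics.
* QALYs are operationalised as the difference-in-differences of index
  values — the convention the motivating analysis divides by — not a
  time-integrated area under the utility curve; an AUC variant would
  change the effect scale, and is out of scope.
* No discounting (the horizon is 6 months) and no friction-cost
  alternative to the human-capital approach.
* Whether medication costs should be recall-extrapolated like visits is
  not pinned down externally; the package extrapolates all
  questionnaire-window amounts uniformly.
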