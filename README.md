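# trialcea

Trial-based cost-effectiveness analysis for a two-arm randomised trial of
internet-delivered cognitive behaviour therapy (ICBT) versus an active
online control, with body dysmorphic disorder as the motivating
indication.

Health-economic evaluations alongside psychiatric trials ask a single
question: is the intervention's extra benefit worth its extra cost, and to
whom? `trialcea` answers it the way trial health economists do, as a
tested, reusable pipeline:

* **Synthetic trial generation** — a 47-per-arm, three-timepoint trial
  (pre-treatment, post-treatment at 3 months, follow-up at 6 months) with
  arm-specific remission probabilities, EQ-5D utility trajectories with a
  participant random intercept, right-skewed TIC-P style resource-use
  items, and missing-at-random dropout calibrated to published
  per-instrument completion rates. No participant-level data ship with
  the package; everything downstream is testable on generated data.
* **Costing** under three nested perspectives — *clinic* (treatment
  provision only), *health care* (plus other visits and medication) and
  *societal* (plus human-capital productivity losses, domestic cutback
  and unemployment) — with 4-week recall extrapolated to the 12-week
  assessment period and SEK converted to USD at purchasing power parity.
* **Inference** — maximum-likelihood linear mixed models
  `y ~ arm * timepoint + (1 | participant)`; the group-by-time
  interaction coefficient *is* the difference-in-differences (DiD)
  contrast ΔC or ΔE; mixed-logistic remission odds ratios with a marginal
  2x2 fallback; Cohen's *d* from least-squares means.
* **Cost-effectiveness analysis** — ICER = ΔC/ΔE, net monetary benefit
  NB(λ) = λ·ΔE − ΔC, a nonparametric participant-level bootstrap
  (stratified by arm, B = 1000) of the joint (ΔE, ΔC) distribution,
  cost-effectiveness-plane quadrant proportions, and
  cost-effectiveness acceptability curves (CEACs) over a willingness-to-pay
  grid.
* **Sensitivity analyses** — complete cases only (per-analysis
  completeness) and societal costs excluding the volatile unemployment
  category.

Everything takes and returns tibbles, chains with the pipe, and exposes
broom-style `tidy()`/`glance()` methods and `autoplot()`/`plot_ce_plane()`
graphics.

## Worked example

```r
library(trialcea)

cfg <- trial_config()   # 47 per arm, published calibration
report <- run_cea_pipeline(cfg, B = 1000, seed = 1, method = "cellmeans",
                           sensitivity = FALSE)
report
```

```
<cea_report> B = 1000  seed = 1  method = cellmeans 

Point incremental estimates (mixed-model contrasts):
# A tibble: 12 × 6
   timepoint perspective outcome   delta_cost delta_effect  icer
   <chr>     <chr>       <chr>          <dbl>        <dbl> <dbl>
 1 post      societal    qaly            2383        0.095 25002
 2 followup  societal    qaly            2441        0.129 18983
 3 post      societal    remission       2383        0.404  5896
 4 followup  societal    remission       2441        0.422  5781
 5 post      health_care qaly            1115        0.095 11693
 6 followup  health_care qaly            1764        0.129 13714
 7 post      health_care remission       1115        0.404  2757
 8 followup  health_care remission       1764        0.422  4177
 9 post      clinic      qaly             485        0.095  5088
10 followup  clinic      qaly             485        0.129  3772
11 post      clinic      remission        485        0.404  1200
12 followup  clinic      remission        485        0.422  1149

Cost-effectiveness plane quadrant proportions:
# A tibble: 12 × 7
   timepoint perspective outcome      ne    nw    se    sw
   <chr>     <chr>       <chr>     <dbl> <dbl> <dbl> <dbl>
 1 followup  clinic      qaly      0.998 0.002 0     0
 2 followup  clinic      remission 1     0     0     0
 ...
11 post      societal    qaly      0.969 0.022 0.007 0.002
12 post      societal    remission 0.991 0     0.009 0
```

Reading the societal rows: on this simulated realisation the intervention
arm cost \$2383 more per participant by post-treatment and produced 0.404
more remissions per participant, so one additional remission costs
\$5896 (the ICER); one additional QALY costs \$25,002. Nearly all
bootstrap replicates fall in the northeast quadrant of the
cost-effectiveness plane — more effective *and* more costly — so the
decision hinges on willingness to pay:

```r
curves <- ceac(report$replicates)
autoplot(curves)                       # probability cost-effective vs lambda
plot_ce_plane(report$replicates)       # the bootstrap cloud itself
```

Note that a single 47-per-arm trial is noisy: incremental societal costs
have a standard error above \$1000, so a realisation's ICER can sit well
away from the generating values (here the expected ΔC is \$1231 and
expected post-treatment remission difference 0.30). The bootstrap cloud,
not the point ICER, is the inferential object.

Individual stages compose with the pipe:

```r
trial <- simulate_trial(cfg, seed = 1) |> apply_missingness(cfg)
analysis <- build_analysis_table(trial, cfg$tariff)
fit <- fit_outcome_model(analysis, "eq5d_index")
tidy(fit)                  # fixed effects
did_contrast(fit, "followup")
```

## Where things live

| | |
|---|---|
| `R/simulate.R`, `R/trial_config.R` | synthetic trial generator and calibration |
| `R/costing.R` | tariffs, costing rules, perspectives |
| `R/outcomes.R` | EQ-5D value sets and utility indexing |
| `R/inference.R` | mixed models, contrasts, effect sizes, odds ratios |
| `R/cea.R` | ICER, net benefit, bootstrap, quadrants, CEAC |
| `R/sensitivity.R` | complete-case and unemployment-exclusion variants |
| `R/pipeline.R` | `run_cea_pipeline()` and the report bundle |
| `vignettes/trial-cea-methods.Rmd` | the methods account: models, assumptions, design choices |
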