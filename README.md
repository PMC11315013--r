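# bedtherm

Unobtrusive estimation of distal skin temperature (DST) from a smart-bed
temperature sensor strip.

## Why

The wake–sleep transition is thermoregulatory: peripheral vasodilation
dissipates core heat through the skin, raising distal (hands/feet) skin
temperature by about 1 °C and proximal (trunk) temperature by about 0.5 °C
around sleep onset. Tracking DST night after night normally needs a worn
sensor. A strip of five temperature sensors embedded just below a mattress
surface can do it unobtrusively — but the strip reads a contact-weighted
mixture of skin and bed-microclimate temperature that shifts whenever the
sleeper moves. `bedtherm` is for sleep and circadian researchers who want a
minute-resolution wrist-DST estimate from such a strip, together with the
validation machinery to trust it.

## The method

Per minute *n*, the five strip values are averaged from ~1 Hz samples and
sorted descending; the top three, `V1(n) ≥ V2(n) ≥ V3(n)` (the sensors most
likely under the body), feed a two-stage stacked regression:

```
X(n) = GBT(V1(n), V2(n), V3(n))            # gradient boosted trees
Y(n) = RF(X(n), X(n−1), …, X(n−4))         # random forest on a 5-min window
```

trained sequentially (boosted tree first, then the forest on its
predictions). Sessions are quality-gated (≥ 80% valid minutes in both strip
and reference; null/negative/oscillating minutes and bed-absence minutes
discarded). Agreement with the LOWESS-smoothed wrist reference `S(n)` is
summarized per session by Bland–Altman statistics and R²:

```
bias = mean(S − Y)      LoA = bias ∓ 1.96 · SDd      R² = 1 − SS_res/SS_tot
```

aggregated session → fold → grand mean under subject-blocked 5-fold
cross-validation (no participant in both training and validation). In-lab
verification correlates grand-average change curves (value minus the
lights-off value, minutes 0–60) of the estimated DST against the measured
foot temperature. A synthetic multi-subject generator — quantized,
jittered, artifact-contaminated sensor streams around a latent vasodilation
trajectory — makes the whole pipeline testable without human data.

## Worked example

```r
library(bedtherm)

study <- simulate_study(20, 5, 18, 2, physio_params(), artifact_spec(),
                        seed = 11, duration = 240)
prep  <- preprocess_study(study)
cv    <- run_cv(prep, seed = 11)
cv
#> Subject-blocked 5-fold cross-validation (100 sessions)
#> # A tibble: 5 × 6
#>    fold n_sessions     bias lower_loa upper_loa    r2
#>   <int>      <int>    <dbl>     <dbl>     <dbl> <dbl>
#> 1     1         20 -0.00935   -0.0849    0.0662 0.951
#> 2     2         20  0.0108    -0.0523    0.0739 0.957
#> 3     3         20 -0.00882   -0.0702    0.0526 0.974
#> 4     4         20  0.0315    -0.0320    0.0951 0.962
#> 5     5         20 -0.0121    -0.0685    0.0443 0.973
#> grand means: bias 0.002 degC, LoA [-0.06, 0.07] degC, R2 0.96

model <- train_sequential(prep[prep$setting == "home" & prep$included, ],
                          seed = 11)
verify_in_lab(study, model)
#> Grand-average change curves (29 vs 29 sessions): Pearson r = 0.999, p = 3.45e-83
```

Reading the output: each fold's numbers are unweighted means over its ~20
held-out sessions. A bias of 0.002 °C says the estimate is centred on the
reference; limits of agreement of ±0.07 °C bound 95% of the per-minute
errors on this synthetic study; R² = 0.96 is the share of reference
variance the estimate explains. The verification line says the estimated
DST and the independently measured foot temperature rise in near-lockstep
after lights-off (a handful of lab sessions whose estimate does not yet
cover the lights-off minute are skipped with a warning). `tidy(cv)` /
`glance(cv)` return the fold and grand summaries as tibbles, and
`autoplot()` works on CV, verification and learning-curve objects.

A thin command-line front end is included:

```sh
Rscript inst/cli/bedtherm.R simulate --subjects 2 --nights 2 --seed 7 --out sessions/
Rscript inst/cli/bedtherm.R cv --seed 11 --out results/
```

## Package tour

- `R/simulate.R` — latent thermoregulation model, sensor sampling and
  quantization, artifact injection, study fixtures.
- `R/preprocess.R` — minute aggregation, validity flags, bed-absence
  masking, quality gate, top-three selection, LOWESS reference smoothing.
- `R/estimator.R`, `R/tune.R` — sequential two-stage training, windowed
  prediction, model persistence, TPE-style hyperparameter search.
- `R/evaluate.R` — Bland–Altman/R², subject folds, cross-validation,
  learning curves, change-curve verification.
- `R/io.R`, `R/cli.R`, `R/plots.R` — CSV/JSON/YAML interchange, pipeline
  runner, command line, ggplot2 graphics.

See `vignettes/bedtherm-methods.Rmd` for the model assumptions, parameter
defaults, generator calibration and known limitations.
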