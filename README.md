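# quitmiss

Selection-model and repeated-attempts analyses of *why* a binary trial
outcome is missing, built for smoking cessation trials with heavy loss to
follow-up.

## The problem

Smoking cessation trials routinely lose half their participants to
follow-up and then impute "missing = smoking" (the Russell standard).  That
is a single-imputation procedure resting on an extreme assumption: it is
equivalent to an infinitely strong association between the outcome and its
own missingness.  `quitmiss` provides the tools to *examine* that
assumption with the trial's own data:

1. **Selection model.**  A logistic outcome model
   `logit P(Y=1|x) = α₀ + α₁ᵀx` paired with a logistic missing-data model
   `logit P(R=1|Y=y,x) = β₀ + β₁ᵀx + β₂y`, fitted by maximising the full
   marginal likelihood in which each nonresponder's unobserved outcome is
   summed out.  `β₂` is the adjusted log odds ratio between outcome and
   response: `β₂ = 0` is MAR, `β₂ = −log(IMOR)`, and large positive `β₂`
   approaches "missing = smoking".  Because `β₂` is weakly identified, the
   package supports a sensitivity analysis over fixed `β₂ ∈ {−4,…,4}` with
   warm starts expanding outward from the MAR fit, plus the (fragile) full
   MNAR fit.  Standard errors come from the numerically differenced
   observed information matrix.
2. **Repeated-attempts model.**  When up to ten phone calls and a final
   email are made to obtain the outcome, each attempt `m` gets its own
   intercept: `logit P(R′ₘ=1|Y=y,x) = β₀,ₘ + β₁ᵀx + β₂y` (email = attempt
   11).  The attempt-level likelihood uses much more information than the
   marginal response indicator and identifies `β₂` with a usable standard
   error.
3. **Nonresponder posteriors.**  Bayes' theorem converts a fitted attempts
   model into `P(Y=1 | all attempts failed, x)` per nonresponder, the
   cohort-average of which estimates the abstention rate among the missing,
   with a `β̂₂ ± 2·SE` sensitivity band.
4. **Synthetic cohorts.**  A generator with known ground truth (covariate
   marginals, outcome model, attempt process, outcome-independent call
   budgets) emulating an Internet-based cessation trial: n = 1758, ~59%
   missing outcomes, ~22% abstention among responders.  A shadow-truth side
   table enables calibration and recovery checks that real data cannot
   provide.

## Worked example

```r
library(quitmiss)

co  <- generate_cohort(default_iquit_config(), seed = 3)
summarize_missingness(co)
#> missing: 1035/1758 (59%); abstained among responders: 165/723 (23%)

# sensitivity analysis: IMOR conversion of the grid
round(beta2_to_missing_abstention(-4:4), 2)
#> 0.94 0.85 0.68 0.44 0.22 0.10 0.04 0.01 0.01

# repeated-attempts MNAR fit
fit <- fit_mnar_attempts(co)
round(c(beta2 = fit$params$beta2, se = fit$se[["beta2"]]), 3)
#>  beta2     se
#>  0.079  0.225

# what fraction of the nonresponders does the model think abstained?
band <- beta2_band(fit, co)
round(c(point = attr(band, "point"), band), 3)
#>  point    low   high
#>  0.206  0.178  0.231
```

The implied-abstention row is the sensitivity-analysis header: fixing
`β₂ = −4` says a typical nonresponder abstained with probability 0.94
(implausible), `β₂ = 4` says below 0.01 ("missing = smoking").  On this
synthetic cohort (generated with true `β₂ = 0.215`) the attempts model
estimates `β̂₂ = 0.08 (0.23)` — within sampling error of the truth, a
reminder of how weak the information on `β₂` is at n = 1758 even from
attempt-level data — and puts the nonresponder abstention rate at 0.21
with band (0.18, 0.23): below the responders' 23%, but nowhere near
"missing = smoking"'s 0.

The trend diagnostic on the packaged attempt-count table (quit proportion
versus number of calls needed to reach the responder):

```r
attempt_trend_regression(load_fixture("table3"))
#>       slope          se
#> -0.02922754  0.04270528
```

## Command line

```sh
Rscript -e 'quitmiss::quitmiss_cli()' simulate --seed 1 --out-dir runs
Rscript -e 'quitmiss::quitmiss_cli()' sensitivity --input runs/cohort.csv --grid=-4..4 --out-dir runs
Rscript -e 'quitmiss::quitmiss_cli()' report --input runs/cohort.csv --out-dir runs
```

Subcommands: `simulate`, `summarize`, `fit-selection`, `sensitivity`,
`fit-attempts`, `diagnostics`, `posterior`, `robustness`, `report`.  Every
run writes a JSON log (seed, versions, convergence flags, wall time).

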