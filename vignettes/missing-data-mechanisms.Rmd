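---
title: "Modelling the missing-data mechanism for a binary trial outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the missing-data mechanism for a binary trial outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quitmiss)
```

## The models

`quitmiss` addresses a question that arises whenever a trial's binary
outcome $Y_i$ (here: prolonged smoking abstinence) is missing for many
participants: *what does the pattern of nonresponse tell us about the
missing outcomes themselves?*  All modelling is built from two logistic
components sharing a covariate vector $x_i$ of ten complete baseline
variables (treatment, age, sex, qualifications, deprivation,
conscientiousness, determination, support, dependence, previous failed
quit attempt — always in this order):

* outcome model: $\operatorname{logit} P(Y_i=1 \mid x_i) = \alpha_0 + \alpha_1^\top x_i$;
* selection (missing-data) model:
  $\operatorname{logit} P(R_i=1 \mid Y_i=y_i, x_i) = \beta_0 + \beta_1^\top x_i + \beta_2 y_i$,

where $R_i$ indicates whether $Y_i$ was observed.  The joint law factorises
as outcome model × selection model; responders contribute
$P(Y_i=y_i\mid x_i)\,P(R_i=1\mid y_i,x_i)$ to the likelihood and
nonresponders contribute $\sum_{y\in\{0,1\}} P(Y_i=y\mid x_i)\,P(R_i=0\mid y,x_i)$ —
the unobserved outcome is summed out, so every participant informs the fit
(`selection_loglik()`, evaluated with log-sum-exp stabilisation so that
$|\beta_2|$ up to the "missing = smoking" proxy of 15 does not overflow).

$\beta_2$ is the adjusted log odds ratio between outcome and response.  It
is also minus the log of the informatively missing odds ratio (IMOR), which
gives the interpretable conversion implemented by
`beta2_to_missing_abstention()`: for a typical participant whose
complete-case abstention probability is $p_{cc}$, the implied abstention
probability among nonresponders is
$\operatorname{logit}^{-1}(\operatorname{logit}(p_{cc}) - \beta_2)$.
Because the odds ratio is symmetric in its two margins, this identity holds
exactly on any full 2×2 joint law (a property the test suite checks).

### Why a sensitivity analysis

Jointly estimating $\beta_2$ from the marginal response indicator is
notoriously fragile: the model is identified only through the linearity and
no-interaction assumptions of the selection model.  `fit_full_mnar()` is
provided, but the recommended workflow is `sensitivity_grid()`: fix
$\beta_2$ at each of $-4,\dots,4$, maximise over everything else
(`fit_fixed_beta2()`), and inspect how covariate conclusions move.  Warm
starts expand outward from the MAR anchor — the MAR fit seeds $\beta_2 =
\pm 1$, those fits seed $\pm 2$, and so on — because adjacent fixed values
have nearby optima.  At $\beta_2=0$ the likelihood separates exactly into
two ordinary logistic regressions (complete-case outcome regression, and
response regression on all participants), which `fit_mar()` exploits; the
suite asserts the separation identity to $10^{-8}$.

### The repeated-attempts model

When the trial makes up to ten phone calls and, where possible, a final
email to obtain the outcome, the attempt history is far more informative
than the bare indicator $R_i$.  The attempt-level model gives every attempt
its own intercept while sharing the covariate and outcome effects:
$\operatorname{logit} P(R'_{i,m}=1 \mid Y_i=y_i, x_i) = \beta_{0,m} + \beta_1^\top x_i + \beta_2 y_i$,
$m = 1,\dots,11$, with the email always indexed as attempt 11 regardless of
how many calls preceded it.  Its likelihood (`attempts_loglik()`) has four
branches — phone responders, email responders, email nonresponders,
phone-only nonresponders — with empty failure products equal to one, and
nonresponders' outcomes again summed out over their entire failed history.
If every participant receives exactly one phone attempt the model reduces
exactly to the selection model (asserted to $10^{-10}$).  This model
identifies $\beta_2$ with a usable standard error because participants who
needed many attempts stand proxy for those never reached.

### Nonresponder posteriors

`posterior_abstention()` applies Bayes' theorem: posterior odds of
abstention = prior (covariate) odds × likelihood ratio of the failed
attempts.  Averaging over all nonresponders
(`marginal_nonresponse_abstention()`) estimates the abstention rate in the
missing group; `beta2_band()` repeats the computation at
$\hat\beta_2 \pm k\,SE$ (default $k=2$) with the *other* parameters held at
their estimates.  That "plug-in" construction is the default deliberately:
it isolates the sensitivity to $\beta_2$ alone; a refit-per-$\beta_2$
variant is available via `refit = TRUE`.  The posterior is strictly
decreasing in $\beta_2$, so the band endpoints come from the $+k$ (lower)
and $-k$ (upper) shifts.

## Numerical choices

* **Optimiser.**  Internally, covariates are centred and scaled
  (coefficients are back-transformed exactly — the map is linear; age stays
  in raw years in all reported output).  BFGS (`stats::optim`, reltol
  $10^{-9}$) is followed by a damped Newton polish using the analytic score
  and a differenced Hessian; convergence requires gradient max-norm
  $< 10^{-6}$, and failures are flagged on the fit object, never silently
  ignored.
* **Standard errors.**  Observed information (negative Hessian of the
  log-likelihood at the optimum), obtained by central-differencing the
  analytic score with step $10^{-5}\max(1,|\theta_j|)$.  Observed rather
  than expected information is the right choice under MAR/MNAR likelihood
  analysis.  A singular or non-positive-definite information matrix yields
  `NA` standard errors plus a diagnostic note.
* **Degenerate inputs.**  Cohorts with no nonresponders (the missingness
  regression is vacuous), no responders, or only one outcome class among
  responders raise errors; attempt numbers absent from a (sub)dataset are
  dropped from the parameter vector rather than fixed, which keeps subgroup
  refits identifiable.
* **"missing = smoking".**  Treated as a large finite $\beta_2$ (15 by
  convention) rather than infinity; the sensitivity grid's $\beta_2=4$
  already implies an abstention probability below 0.01.
* **$p_{cc}$ convention.**  Conversions default to the exact complete-case
  rate 162/722 ≈ 0.2244; the rounded 0.22 is accepted via the `p_cc`
  argument.  The two conventions agree to two decimals everywhere on the
  $-4..4$ grid except $\beta_2=1$ (0.094 vs 0.096, printing as 0.09 vs
  0.10), which is why the exact rate is the default.

## What the synthetic generator does and does not emulate

`default_iquit_config()` states a world matching the published margins of
the motivating trial: n = 1758; treated 877/1758; female 1126/1758; age drawn from a
normal with SD 11 truncated to 18–80 and rounded, its location solved so
that the *truncated* mean is exactly 38 (the truncation shrinks the
realised SD to about 10.4); the five score covariates drawn from
discretised normals over their stated supports with the stated means/SDs;
907/1758 with a previous failed quit attempt.  The attempt-side
coefficients are the published attempts-model estimates ($\beta_2=0.215$,
age 0.021, support 0.093, …).  The outcome intercept ($\alpha_0=-2.73$) and
the eleven attempt intercepts were calibrated once against a large
simulation so that missingness is ≈ 59% and complete-case abstention ≈ 22%,
then frozen; they are not tuned per seed or per test.  The phone-call
budget (60% of participants reachable for one call only, 36% for ten —
matching the published table's implied continuation pattern of "mass at one
call plus an email") is drawn independently of the outcome, which encodes
the analysis models' own assumption that attempt cessation (invalid
numbers, refusals) is non-informative.

Deliberate simplifications, hence limits on what a green test establishes:
covariates are drawn independently (the real joint law is unpublished);
call cessation is outcome-independent by construction; the generator uses
exactly the fitted model's functional form, so recovery tests validate the
estimator, not the model's adequacy for real data.  The generator retains
every participant's true outcome in a shadow side table
(`shadow_truth()`), used by calibration tests and never by fitting code.

## Testing and acceptance conventions

Every likelihood is checked against an independent brute-force enumeration
oracle (longhand `exp/(1+exp)` loops over all missing-outcome
configurations) on small mixed-branch cohorts, to $10^{-8}$ or better.
Fixed-$\beta_2$ fitting is checked against an exhaustive grid-search
maximiser on a 50-participant, one-covariate problem.  Parameter-recovery
acceptance runs 20 seeded replicates at n = 20,000 (reduced from 50 to keep
the suite within its runtime budget): the *selection* model is fitted to
single-attempt cohorts, where the generator coincides exactly with the
selection model; the *attempts* model is fitted to full multi-attempt
cohorts.  "Recovery within 3 reported SEs in ≥ 95% of replicates" is
evaluated parameter-wise (the pooled fraction of parameter×replicate checks
within 3 SEs), because with ~21–33 parameters per fit the per-replicate
all-parameters-jointly reading would have an expected pass rate of about
$0.997^{21} \approx 0.94$ even for a perfectly calibrated estimator.
Wald-interval coverage for $\hat\beta_2$ in the attempts model is required
in ≥ 90% of replicates.

## Known limitations

* No pattern-mixture or shared-parameter reformulations, no Bayesian
  fitting, no covariate selection, and no separate $\beta_2$ for the email
  attempt (the data would identify it no better than the marginal selection
  model identifies its $\beta_2$); the email-depends-on-calls robustness
  variant is the supported relaxation.
* Categorical covariates are used as numeric scores; `coding_adequacy_tests()`
  provides the deviance-test justification on any given dataset, but no
  spline or fractional-polynomial alternatives are offered.
* Posteriors are reported, not imputed: the package does not produce
  completed datasets.
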