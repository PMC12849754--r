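# ahadjust

Confounding-adjusted inference for the **average hazard** of right-censored
time-to-event outcomes in comparative effectiveness research.

## The problem

Observational comparisons of two treatment groups on a survival endpoint
face two entangled difficulties: the groups differ in case-mix
(confounding), and follow-up is censored. The average hazard (AH) over a
clinical window \[0, τ\] is a summary of the event-time distribution that
is interpretable as an average person-time incidence rate free of the
censoring distribution:

    η(τ) = ∫₀^τ h(u) S(u) du / ∫₀^τ S(u) du  =  {1 − S(τ)} / ∫₀^τ S(u) du,

i.e. the cumulative incidence at τ divided by the restricted mean survival
time (RMST). Group effects are summarized absolutely and relatively by the
difference and ratio of average hazards,

    DAH = η₁(τ) − η₀(τ),      RAH = η₁(τ) / η₀(τ).

Because both are functionals of the group survival curves, any method that
produces *adjusted* survival curves yields confounding-adjusted AH
inference. `ahadjust` implements seven such methods behind one interface:

| name | method | working model |
|---|---|---|
| `km` | group-wise Kaplan-Meier (unadjusted reference) | none |
| `ds` | direct standardization / G-formula via a Cox model | outcome |
| `iptw_km` | inverse probability of treatment weighted KM | treatment |
| `iptw_ch` | IPTW exponentiated Nelson-Aalen cumulative hazard | treatment |
| `matching` | bidirectional 1:1 propensity-score matching (ATE) | treatment |
| `el` | empirical-likelihood covariate-moment balancing | treatment terms |
| `aiptw` | augmented IPTW with censoring weights (doubly robust) | outcome + treatment (+ censoring) |

Standard errors and 95% confidence intervals come from a nonparametric
bootstrap that re-runs the complete pipeline — model fits, weights or
matches, curves, estimands — on every resample (log scale for RAH).

A simulation engine generates confounded survival data under configurable
scenarios, computes oracle true values by counterfactual Monte Carlo, and
summarizes estimator performance (mean relative bias, rMSE, coverage,
median CI length).

## Worked example

```r
library(ahadjust)

set.seed(7)
ds <- make_dataset(300, scenario = 1, censoring = "A")  # confounded cohort
spec <- case_model_spec(1)                              # correctly specified models

est <- bootstrap_inference(ds, "aiptw", spec, tau = 0.7,
                           cfg = bootstrap_config(B = 300, seed = 1))
est
```

```
Average hazard summary (tau = 0.7, method = aiptw)
  eta0   1.7401  (95% CI 1.4712 to 2.0091)
  eta1   0.8699  (95% CI 0.6446 to 1.0952)
  DAH    -0.8702  (95% CI -1.1732 to -0.5673)
  RAH    0.4999  (95% CI 0.3841 to 0.6507)
  bootstrap: 300 resamples, 0 failed
```

Here `eta0`/`eta1` are the adjusted average hazards (events per person-time
over \[0, 0.7\]) in the control and treated groups; treatment roughly
halves the average hazard (RAH 0.50) and the CI for the difference
excludes zero. The matching oracle truth for this data-generating process
is DAH ≈ −0.79, RAH ≈ 0.54 (`true_values(1)`).

Several methods at once, in the shape of a results table:

```r
ah_estimate(ds, methods = c("km", "ds", "aiptw"), spec = spec, tau = 0.7,
            boot = bootstrap_config(B = 300, seed = 1))
```

From a file, via the bundled command-line wrapper:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "ahadjust-cli.R", package="ahadjust"))') \
  estimate --data cohort.csv --methods km,ds,aiptw \
  --outcome X1,X2,X4,X5^2 --treatment X2,X3,X5,X6 --tau 0.7 --boot 300
```

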