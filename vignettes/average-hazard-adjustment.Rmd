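---
title: "Adjusted average-hazard inference: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjusted average-hazard inference: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahadjust)
```

## The estimand

For an event time $T$ with survival function $S$ and hazard $h$, the
average hazard over a prespecified window $[0, \tau]$ is

$$\eta(\tau) \;=\; \frac{\int_0^\tau h(u)\,S(u)\,du}{\int_0^\tau S(u)\,du}
\;=\; \frac{1 - S(\tau)}{\int_0^\tau S(u)\,du},$$

the cumulative incidence at $\tau$ per unit of restricted mean survival
time (RMST). Unlike the crude person-time incidence rate
$\sum_i \Delta_i / \sum_i Y_i$, which depends on the censoring
distribution unless $T$ is exponential, $\eta(\tau)$ is a functional of
the event-time law alone. Its units — events per person-time — give it a
direct epidemiological reading; an exponential distribution has
$\eta(\tau)$ equal to its rate at every $\tau$ (a property the test suite
checks numerically). Group contrasts are the difference
$\mathrm{DAH} = \eta_1 - \eta_0$ and ratio
$\mathrm{RAH} = \eta_1/\eta_0$; the latter is *not* the
Kalbfleisch–Prentice average hazard ratio, which averages time-specific
hazard ratios instead.

Everything in this package estimates $\eta_j(\tau)$ by plugging a step
survival curve $\hat S_j$ into the identity above. RMST is computed by
exact rectangle summation over the step curve — never quadrature — so
$\hat\eta_j(\tau) \cdot \widehat{\mathrm{RMST}}_j(\tau) = 1 -
\hat S_j(\tau)$ holds to machine precision and the three summaries can
never be mutually inconsistent.

## The seven curve constructions

All methods share one contract: consume a dataset $(Y_i, \Delta_i, Z_i,
X_i)$, emit a pair of right-continuous non-increasing step curves on the
grid of observed event times. Each differs only in how case-mix enters.

* **`km`** — group-wise Kaplan-Meier, no adjustment; the reference that
  quantifies what confounding costs.
* **`ds`** — G-formula: a Cox model with treatment plus the outcome
  terms; $\hat S_j(t) = n^{-1}\sum_i \hat S(t \mid Z = j, X_i)$. Requires
  the outcome model; tolerates censoring that depends on modeled
  covariates.
* **`iptw_km`, `iptw_ch`** — weighted Kaplan-Meier and weighted
  exponentiated Nelson-Aalen with ATE weights
  $Z_i/\hat\pi_i + (1 - Z_i)/(1 - \hat\pi_i)$ from a logistic propensity
  model. The weights are deliberately unstabilized: within a group, a
  multiplicative constant cancels in every $dN^w/Y^w$ ratio, so
  stabilization cannot change the curves; we document this instead of
  offering a no-op option.
* **`matching`** — 1:1 nearest-neighbour matching on the propensity
  score, with replacement, in *both* directions, so the matched sample
  mirrors the full cohort and the estimand remains the ATE. Distance ties
  break toward the lowest subject index, making the algorithm fully
  deterministic — reproducibility without a matching-specific RNG stream.
* **`el`** — per-group empirical-likelihood weights maximizing
  $\sum \log p_i$ subject to the group's weighted *first moments* of the
  treatment-model covariates equaling the pooled means. We restrict the
  constraint set to first moments because that is the minimal set that
  removes mean imbalance; the dual is solved by damped Newton with
  backtracking that keeps every $1 + \lambda^\top c_i$ positive, and
  convergence is declared on the weighted-moment violation (not the raw
  dual gradient, which also vanishes when $\lambda$ diverges on
  infeasible problems — those are reported as a typed
  `ahadjust_el_error`). When groups are already balanced the solution is
  exactly uniform and `el` collapses to `km`.
* **`aiptw`** — the one-step augmented estimator of the cumulative
  incidence,
  $$\hat F_j(t) = n^{-1}\sum_i \left[\hat F(t \mid j, X_i) +
  \frac{I(Z_i = j)}{\hat\pi_j(X_i)}\left\{\frac{I(Y_i \le t, \Delta_i =
  1)}{\hat G(Y_i^- \mid Z_i, X_i)} - \hat F(t \mid j, X_i)\right\}\right],$$
  combining the outcome model, the propensity model, and inverse
  probability of censoring weights. It is consistent if either the
  outcome or the treatment model is correct, provided the censoring model
  is. We use this IPCW-augmented form without the additional
  censoring-martingale efficiency term: it matches the stated consistency
  conditions with substantially less machinery, at a small efficiency
  cost. Raw augmented curves need not be monotone; we clip to $[0,1]$ and
  apply a running minimum, and the number of repaired grid points is
  surfaced in the diagnostics rather than hidden.

Nuisance fits are standard: unpenalized IRLS logistic regression (score
floored to $[10^{-6}, 1 - 10^{-6}]$; no substantive trimming by default),
Cox partial likelihood with the Efron tie correction and a Breslow
baseline hazard (ties are measure-zero under the continuous simulation
law, so this pairing matters only for user data, where Efron is the safer
default), and a censoring-survival model that is a pooled Kaplan-Meier
under independent censoring or a Cox model when censoring depends on
covariates. IPCW evaluates the censoring survival at the *left limit*
$\hat G(Y_i^-)$ so a subject's own censoring jump cannot deflate its
weight. The censoring Cox model uses only the specified censoring terms
(no treatment indicator), which is the form the covariate-dependent
simulation pattern calls for.

## Inference

Confidence intervals come from a nonparametric bootstrap (default $B =
300$) that resamples subjects and re-runs the complete pipeline — fits,
weights, matches, curves, estimands — per resample. The SE is the sample
SD of the resample estimates, on the log scale for RAH, and intervals are
normal-approximation intervals (symmetric for DAH, log-symmetric for
RAH); percentile and BCa intervals are out of scope. Choices worth
recording:

* **Unstratified resampling** by default, matching a single-cohort
  sampling model in which group membership is itself random; a
  `stratified` flag resamples within groups for designs with fixed group
  sizes.
* **Failed resamples are skipped and counted**, never redrawn: redrawing
  conditions the bootstrap distribution on success and hides fragility.
  If fewer than `min_valid_fraction` (default 0.8) of resamples succeed,
  inference aborts with a typed error listing the failure reasons.
* **Substream seeding**: resample $b$ derives its seed from the pair
  (master seed, $b$), so enlarging $B$ extends rather than reshuffles the
  resample sequence, and simulation cells can run in any order with
  bit-identical results.

## What the simulation engine emulates

The generator reproduces a six-covariate confounded cohort: three binary
and three continuous covariates with mild dependence (`X2` on `X3`, `X5`
on `X6`), logistic treatment assignment driven by `X2, X3, X5, X6`,
event times that are conditionally Weibull (Scenario 1) or exponential
(Scenario 2) with hazard increased by `X1, X2, X4, X5²` and *decreased* by
treatment, and exponential censoring capped administratively at time 1.0
(rates 0.1, 0.2, or `0.01 + 0.4·X2` for covariate-dependent censoring).
These defaults are the study conditions themselves, not tuning knobs. The
confounder `X2` raises both treatment probability and event hazard, so
the unadjusted contrast is biased toward the null — the five
`case_model_spec()` variants probe what each method does when `X2` is
present, absent, or accompanied by irrelevant extras in each working
model.

True parameter values come from a counterfactual oracle: 10,000 covariate
draws, event times generated under $Z = 1$ and $Z = 0$ with shared
covariates and independent uniforms per arm (the estimand is marginal, so
common random numbers are a variance choice, not a correctness one — we
use independent draws), uncensored plug-in estimation, averaged over 100
repetitions. At these sizes the Monte Carlo SE of every parameter is
below 0.005.

What the generator does *not* emulate: tied event times, covariate
measurement error, informative censoring beyond the modeled covariate,
non-proportional conditional hazards, or treatment effects that vary with
covariates. Passing tests therefore demonstrate correctness of the
estimators under a clean, continuous, correctly-parameterized law — they
do not certify behavior on real registries, where ties and positivity
violations are the rule.

## Numerical choices and degenerate inputs

* Follow-up times must be strictly positive; this guarantees RMST $> 0$
  and keeps every average hazard finite.
* Ties between events and censorings at one time: events first (standard
  Kaplan-Meier convention).
* A curve evaluated beyond its last supporting time carries the last
  value forward; `rmst()` warns when this extension is actually used
  (it arises in bootstrap resamples whose largest follow-up is below
  $\tau$).
* $\hat\eta_0 = 0$ (no control-group events by $\tau$): DAH is still
  returned, RAH is `NA` rather than an error, so simulation replicates
  can be filtered downstream.
* Propensity scores are floored at $10^{-6}$; IPTW warns when the largest
  weight exceeds ten times the median.
* All failures are typed conditions (`ahadjust_input_error`,
  `ahadjust_fit_error`, `ahadjust_el_error`, `ahadjust_ipcw_error`,
  `ahadjust_inference_error`) — no silent `NaN`s; the simulation engine
  counts them per method and flags any cell with more than 20% failures.

## Problem sizes used by the shipped checks

The package's own verification runs at desk scale, chosen to keep the
full suite inside a coffee break while leaving Monte Carlo error well
below the tolerances asserted: bias and rMSE cells use 500–2000
replicates of $n = 300$; the coverage cell uses 500 replicates with $B =
200$ bootstrap resamples; large-sample consistency checks use single
replicates of $n = 10^4$ (Cox-based methods) or $n = 10^5$ (weighting
methods, whose cost is linear); the truth oracle always runs at its full
$10{,}000 \times 100$ size. The engine itself accepts the full-scale
profile (2000 replicates, $B = 300$) as plain configuration.

## Known limitations

* The AH regression approach and pseudo-value hybrids are intentionally
  out of scope, as are caliper matching, overlap/ATT weights,
  machine-learned nuisance models, competing risks, left truncation and
  interval censoring.
* Analytic (non-bootstrap) variances are not provided; bootstrap cost is
  the price of uniform treatment across methods. In particular, treating
  a matched sample as independent replicates with Greenwood's variance
  would understate uncertainty — the bootstrap re-matches every resample
  instead.
* Our empirical-likelihood estimator balances first moments only and, in
  the simulated conditions, is noticeably *less* variable than typical
  published EL-balancing implementations; its relative-efficiency ranking
  against matching should not be read as a general statement about EL.
* The standardized stratified AH (`standardized_ah()`) coincides with the
  marginal AH exactly only when every group carries the stratum
  composition of the pooled sample and censoring is absent; with
  censoring it is a distinct, stratification-based adjustment. The AH is
  not collapsible: a $\pi$-weighted average of stratum AHs is *not* the
  standardized AH, and the package exposes both quantities so the
  difference is visible rather than papered over.
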