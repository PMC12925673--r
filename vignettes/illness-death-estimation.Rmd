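---
title: "Estimating incidence and remission from repeated cross-sectional prevalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating incidence and remission from repeated cross-sectional prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idmrates)
```

# The model and its assumptions

`idmrates` estimates age-specific incidence and remission rates of a
remitting chronic condition from two cross-sectional prevalence surveys,
general mortality rates, and condition-specific mortality rate ratios.
The engine is the three-state illness-death model: susceptible,
diseased, dead, with transitions incidence $i(a)$, remission $r(a)$, and
mortality $m_0(a)$ (susceptible) and $m_1(a)$ (diseased), all per
person-year. Along a cohort's life line, point prevalence $p(t,a)$
satisfies

$$(\partial_t + \partial_a)\,p = (1-p)\,i - p\,r - p(1-p)(m_1 - m_0).$$

Since $m_0$ is rarely observed, `pde_rhs_mrr()` substitutes the general
mortality $m = (1-p)m_0 + p\,m_1$ and the mortality rate ratio
$R = m_1/m_0$, so that $m_0 = m/(1 + p(R-1))$ and the last term becomes
$p(1-p)\,m\,(R-1)/(1+p(R-1))$. The two forms are algebraically
identical whenever the inputs are consistent, and the test suite holds
them to within $10^{-12}$ on random parameter grids.

The key structural assumptions, shared with the estimation target:

* **Time-constant rates within the observation window.** With two
  cross-sections only three calendar years apart, time trends in $i$
  and $r$ are not identifiable; the calendar-time term of the
  prevalence model absorbs level shifts.
* **Unimodal rate curves.** Incidence and remission are single
  Gaussian bumps $A \exp\{-((a-\mu)/w)^2\}$ — amplitude $A$ (rate at
  the mode), location $\mu$ (years), width $w > 0$ (years). The width
  enters as a scale, not a variance: the three parameters are then all
  interpretable on the age axis, the value at the mode is exactly $A$,
  and the curve integrates to $A w \sqrt{\pi}$. This parameterization
  is a documented modelling choice; a variance-scaled or log-amplitude
  variant would span the same family.
* **Screeners define the state.** "Diseased" means scoring above the
  instrument cut-off; rates refer to the probable-case state, not
  clinical diagnoses.

# The prevalence surface

`fit_logit_polynomial()` maximizes the survey-weighted binomial
likelihood of case status with a logit link. The linear predictor
contains a raw polynomial in centered age (`df` terms; ages are centered
at 46.5, the midpoint of 19–74, for conditioning), a linear term in
centered calendar time (period midpoints 2015.5 and 2018.5, centered at
2017), additive sex and center indicators, and by default a linear
age-by-sex interaction — reported rate curves differ by sex, while the
higher-order curvature is pooled across strata. Whether deeper
age-by-sex-by-center interactions belong in the model is an open
question for real data; the pooled default is the most parsimonious
reading and is what the synthetic test-bed exercises.

Records with a missing case indicator are dropped for that condition
(complete-case analysis; imputation is deliberately out of scope because
the missingness mechanism of screener data is unclear). Weighted case
and total sums are aggregated into (center, sex, period, age) cells —
the binomial likelihood is invariant to this aggregation — and the GLM
is fitted to the cells, which also makes cross-validation affordable.

`prevalence_and_derivative()` returns $p = \operatorname{logistic}(\eta)$
and the directional derivative
$dp = p(1-p)(\partial_t \eta + \partial_a \eta)$ computed analytically
from the coefficients; a central-difference oracle in the tests agrees
to $10^{-6}$.

## Choosing the polynomial degrees of freedom

`select_df_loocv()` performs leave-one-cell-out cross-validation: each
cell is predicted from a refit without it, and squared errors on the
probability scale are averaged with the cells' weighted totals as
weights. The selected df is the *smallest* candidate within one
standard error of the minimizing candidate. The plain minimizer is not
selection-consistent here: an extra polynomial degree wins whenever it
happens to chase noise, which occurs with substantial probability at any
sample size (in our simulations an exactly cubic truth was over-fitted
about a third of the time), whereas the one-standard-error rule selects
the generating degree essentially always and matches the package's
parsimony-first philosophy.

## A caution: prediction error is not derivative error

The surface is a nuisance model — the estimator consumes its
*derivative*. A low-degree polynomial can predict prevalence almost as
well as a higher-degree one while attenuating the derivative near the
age boundary, which biases the recovered incidence peak upward in age.
`noiseless_df_scan()` quantifies this: it fits the surface to the exact
(infinite-data) prevalences of a known truth, runs the estimator, and
reports the peak error per df. For the default truth the scan
recommends df = 4 (peak-age bias 1.4 y) while dfs 2–3 carry a +3.5 to
+5 y bias. Recovery and coverage experiments therefore fit at the
scan-recommended df; survey analyses without a known truth use the
cross-validated df and should read estimated peak locations with this
caveat in mind.

# Mortality inputs

`fit_log_mortality()` and `fit_mrr()` turn tabulated life-table rates
and mortality rate ratio curves into smooth positive functions by
least-squares on the log scale, $\log y(a) = \alpha + \beta a$ — a
Gompertz-type form that fits adult mortality well and guarantees
positivity; exact log-linear inputs are recovered to machine precision.
The robustness analysis multiplies the MRR curve itself (not $R-1$) by
a constant factor, default $\pm 15\%$ (`perturb_mrr()`); the curves are
treated as shared across sexes unless sex-specific tables are supplied.

# Least-squares rate estimation

`eq5_objective()` sums, over integer ages 20–73, the squared difference
between the surface derivative and the balance-equation right-hand side
implied by candidate Gaussian curves. The grid stays strictly inside
the observable range 19–74 so the derivative is interpolated, never
extrapolated; the evaluation time is 2017.0, the midpoint between the
two cross-section midpoints; residuals are unweighted (no residual
weighting is implied by the estimation target).

`estimate_rates()` minimizes the objective over the six coefficients
with Nelder-Mead followed by a BFGS polish, from 8 deterministic starts
that vary the Gaussian locations over {20, 45, 70} and the amplitude
signs. Widths are optimized as logarithms so positivity needs no
bounds, and parameter scaling (amplitudes ~0.005–0.02, locations ~25
years, log widths ~1) keeps the simplex well conditioned. The whole
procedure is deterministic.

Two numerical realities shape the selection among starts:

* **An inadmissible mirror branch.** The derivative of a smooth fitted
  surface can be reproduced almost equally well by a *negative*
  incidence bump at old ages paired with a *negative* remission bump at
  young ages. On sampled data this mirror branch occasionally attains
  a (meaninglessly) smaller sum of squares. The winner is therefore
  the best solution with both amplitudes positive, falling back to the
  overall best only when no start ends on the admissible branch; ties
  break toward the lowest start index. Amplitudes remain unconstrained
  *within* each local search, and genuinely negative point estimates
  are still possible (and are truncated to zero at reporting time).
* **A flat valley.** Near the optimum, amplitude-width-location
  combinations trade off almost perfectly; the coefficients are less
  stable than the rate curves they imply. Comparisons in the tests are
  therefore made on the curves (the estimand), not the raw
  coefficients.

`rates_table()` converts to the reporting units — incidence per 1,000
person-years, remission per 100 person-years — truncating negative
values and confidence bounds to zero with explicit flags.
`find_peaks()` reports the argmax over the closed observable range
19–74; a Gaussian mode outside that range is reported at the boundary
age, mirroring how a study population bounded at 74 can only exhibit
its highest *observable* remission there.

# Bootstrap confidence bands

`bootstrap_rates()` resamples participants with replacement within
(center, period) strata — preserving the two-cross-section design —
carrying their survey weights, and re-runs complete-case filtering, the
prevalence fit and the rate estimation per replicate. Design choices:

* the polynomial df is fixed at the point estimate's df, not
  re-selected per replicate (re-running model selection thousands of
  times is disproportionate, and one selected df is the analysis
  contract);
* each replicate's optimizer warm-starts at the point estimate (a
  single start): replicates perturb the data only slightly, so the warm
  start keeps them on the point estimate's solution branch at a
  fraction of the multistart cost;
* replicate seeds derive from the master seed by a counter
  (`seed + 1000003·b mod 2^31−1`), so the ensemble is reproducible and
  independent of execution order — parallel execution cannot change
  the result;
* replicates whose prevalence fit or optimization fails are dropped and
  counted; more than 20% failures aborts the ensemble.

`percentile_band()` takes the empirical 2.5th/97.5th percentiles per
age (quantile type 7, R's default continuous-sample definition) and
truncates negative bounds to zero *after* the percentile computation;
the untruncated band is retained as an attribute. Only the final band
and point estimates are truncated, never the replicates themselves.
With truncation, `lower ≤ point ≤ upper` can fail only through the
lower bound hitting zero.

# The synthetic test-bed

`make_truth()` builds a fully known illness-death world and derives its
prevalence curve with the forward cohort solver — a fixed-step
(0.1-year) classical fourth-order Runge-Kutta integration of the
balance equation, chosen over adaptive schemes for exact
reproducibility; the solution is clamped to $[0,1]$ and matches
closed-form solutions to well below $10^{-6}$ over 55 years of
integration.

The default configuration, used throughout the tests: anxiety in women
has incidence amplitude 0.004/PY at age 20 (width 18 y), remission
0.04/PY at age 72 (width 20 y), baseline prevalence 0.05 at age 19;
men carry a lower incidence amplitude (0.0027/PY) and baseline (0.035);
depression peaks later (ages 30/31) with higher baseline prevalence
(0.07/0.05), echoing the qualitative pattern of community screening
data. Mortality among the susceptible is Gompertz,
$10^{-4} e^{0.09(a-19)}$, and the mortality rate ratio is a constant 2.
These values are fixed study conditions, not tuning knobs.

`sample_study()` draws, per (center, sex, period) stratum, ages
uniformly on 19–74, Bernoulli case indicators from the truth's
prevalence, mean-one Gamma survey weights (variance 0.2 by default),
and missing-completely-at-random screeners (default 6%, within the
range observed in large German cohort baselines). What the generator
deliberately does *not* emulate: the real cohort's age-stratified
sampling frame, response propensities and weight construction,
item-level screener data, center-specific prevalence differences, or
calendar-time trends. Passing tests therefore demonstrate that the
estimation machinery is correct and stable under the stated model —
not that real screening data satisfy that model.

# Problem sizes and empirical behaviour in the test suite

The validation experiments use scaled study sizes chosen to keep the
full suite fast while leaving the conclusions stable: parameter
recovery uses 20 replicate five-center studies with 25,000 participants
per (center, sex, period) stratum; coverage uses 20 single-center
studies (12,500 per stratum) with 200 bootstrap replicates each;
selection consistency uses 50 replicates of a single-stratum cubic
truth. With the exact truth surface the estimator returns the
generating coefficients to well under 0.1%; on sampled studies the
incidence peak is recovered within ±4 years and ±25% amplitude in the
large majority of replicates; 95% bands cover the true incidence at
ages 25/45/65 in well over 70% of studies; and ±15% MRR perturbation
moves the incidence peak by under 1% while shifting old-age remission
in the expected direction (higher mortality ratio, lower remission).

# Known limitations

* **Weak identifiability.** Two three-parameter Gaussians are inferred
  from one smooth derivative curve; amplitude/width/location trade-offs
  and the mirror branch mean coefficient-level uncertainty is large
  even when the rate curves are tight. Bootstrap bands on the curves
  are the honest uncertainty summary.
* **Boundary peaks.** When the remission mode lies beyond age 74 the
  reported peak is the boundary value; the true mode's location is not
  identified.
* **Misclassification adjustment.** `adjust_prevalence()` implements
  the standard sensitivity/specificity correction, but at single-digit
  observed prevalences typical screener operating characteristics push
  the adjusted value below zero; such values are flagged and must not
  be propagated into rate estimation.
* **Derivative bias at low df.** See the surface-df caution above:
  cross-validated parsimony and derivative fidelity can disagree, and
  with real data there is no oracle scan to arbitrate.
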