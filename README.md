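# idmrates

Age-, sex- and region-specific **incidence and remission rates** of a
remitting chronic condition, estimated from **repeated cross-sectional
prevalence surveys** — no longitudinal follow-up required.

The motivating application is mental-health epidemiology: large baseline
surveys screen participants for moderate-to-severe anxiety or depressive
symptoms (GAD-7 or PHQ-9 sum score ≥ 10), which yields age-specific
*prevalence* at two or more calendar times, but no direct observation of
onset or recovery. `idmrates` reconstructs both from the internal
consistency of the three-state **illness-death model**
(susceptible → diseased → dead, with remission diseased → susceptible).

## The model

Along a birth cohort's life line, point prevalence `p(t, a)` obeys the
balance equation

    (∂t + ∂a) p = (1 − p)·i(a) − p·r(a) − p(1 − p)(m1(a) − m0(a))

with incidence `i`, remission `r`, and mortality among the diseased /
susceptible `m1` / `m0` (all per person-year). Because `m0` is rarely
observed, the package substitutes the general mortality rate `m` and the
mortality rate ratio `R = m1/m0`:

    (∂t + ∂a) p = (1 − p)·i − p·r − p(1 − p)·m·(R − 1) / (1 + p(R − 1))

The pipeline is:

1. **Prevalence surface** — survey-weighted binomial GLM of case status
   with logit link: polynomial in age (df selected by leave-one-out
   cross-validation), linear calendar time, sex, study center, and an
   age × sex interaction. The directional derivative `(∂t + ∂a) p` is
   evaluated analytically through the chain rule.
2. **Mortality inputs** — log-linear (Gompertz-type) fits to a
   life-table of general mortality and to an age-specific mortality
   rate ratio curve.
3. **Rate estimation** — `i(a)` and `r(a)` are single Gaussian bumps,
   `A·exp(−((a − μ)/w)²)`; their six coefficients minimize the summed
   squared discrepancy between the surface derivative and the balance
   equation over ages 20–73 (derivative-free simplex, 8 deterministic
   multistarts, BFGS polish).
4. **Uncertainty** — nonparametric bootstrap of participants within
   (center, period) strata through the whole pipeline; percentile 95%
   bands, negatives truncated to zero at reporting time.
5. **Reporting** — incidence per 1,000 person-years, remission per 100
   person-years, peak ages clamped to the observable range 19–74.

A synthetic-study generator (`make_truth()`, `sample_study()`) draws
two-cross-section multicentre baseline studies from a *known*
illness-death world — the forward Runge-Kutta cohort solver doubles as
the ground-truth oracle — so the whole chain is testable end to end.

## Worked example

Estimate anxiety-symptom rates for women in one region of a synthetic
five-center study (25,000 participants per center × sex × period,
6% missing screeners), generated from a truth with incidence peaking at
0.004/PY at age 20 and remission at 0.04/PY at age 72:

```r
library(idmrates)

truth   <- make_truth()                      # known ground truth
records <- sample_study(truth, n_per_stratum = 25000, missingness = 0.06, seed = 1)

fit  <- fit_logit_polynomial(records, condition = "anxiety", df = 4)
grid <- evaluation_grid("female", "Hamburg")
m    <- fit_log_mortality(make_mortality_table(1e-4, 0.09, sex = "female"))
mrr  <- fit_mrr(make_mrr_curve(2, 0))

est <- estimate_rates(fit, m, mrr, grid)
est
#> Illness-death rate estimate (female, Hamburg): objective 2.88e-09, start 3
#> Illness-death rate parameters
#>   incidence: 0.00449346 /PY at age 20.24 (width 18.13 y)
#>   remission: 0.215498 /PY at age 125 (width 44.13 y)

ens <- bootstrap_rates(records, "anxiety", df = 4, m, mrr, grid,
                       B = 200, seed = 1, point = est)
rates_table(est, ages = c(20, 30, 45, 60, 70), band = percentile_band(ens))
#>   age incidence_per_1000py  inc_lo inc_hi remission_per_100py rem_lo rem_hi
#> 1  20               4.4927 3.9e+00  5.168               0.075 0.0084   0.65
#> 2  30               3.3634 2.8e+00  4.278               0.210 0.0452   1.01
#> 3  45               0.6964 2.1e-01  1.999               0.807 0.3573   1.85
#> 4  60               0.0367 1.7e-03  0.398               2.465 1.6904   3.47
#> 5  70               0.0024 2.1e-05  0.093               4.564 3.4547   5.72

find_peaks(est)
#>        rate      age       value at_boundary
#> 1 incidence 20.24062 0.004493462       FALSE
#> 2 remission 74.00000 0.056740715        TRUE
```

The estimated incidence peak (4.49/1,000 PY at age 20.2) recovers the
generating truth (4.0/1,000 PY at age 20) within the bootstrap band.
The remission Gaussian's mode falls beyond the study's upper age limit,
so its peak is reported at the boundary age 74 — exactly the situation
that arises with late-life remission in real screening data. The full
orchestration (`run_study_analysis()` + `write_outputs()`) runs every
condition × sex × center stratum from one configuration list and emits
CSV tables, coefficient JSONs, an MRR-sensitivity comparison and a run
log.

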