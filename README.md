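# recurtte

Parametric time-to-event modelling of **recurrent ischemic stroke** after an
index stroke, for epidemiologists and pharmacometricians working with
registry-style cohorts (one row per patient: follow-up years, event
indicator, binary comorbidity/treatment covariates).

Unlike a Cox analysis, the baseline hazard is modelled explicitly as a
piecewise parametric function, so the recurrence risk is predictable at any
time after the index stroke. The model is

```
S(t) = exp(-∫₀ᵗ h(s) ds),   h_i(t) = h₀(t) · exp(β₁x_i1 + … + βₙx_in + η_i)
```

with a piecewise baseline `h₀(t)` whose segments are constant (`θ`),
Gompertz (`θ·exp(βt)`) or Weibull (`θ·t^β`), proportional-hazards effects
of binary covariates (hazard ratio `exp(β)`), and an optional log-normal
frailty `exp(η)`, `η ~ N(0, ω²)`, integrated by the Laplace approximation.
The packaged default is a two-phase recurrence hazard: scale switch at 6
months, shape switch at 3 years, covariate effects of hyperlipidemia,
ischemic heart disease, hypertension, and antiplatelet therapy.

The package covers the full analysis cycle:

* **cohort I/O** — CSV read/write with schema mapping (NONMEM-style
  `ID/TIME/DV` headers accepted), strict row validation, Table-1-style
  summaries (`read_cohort`, `write_cohort`, `summarize_cohort`);
* **hazard engine** — closed-form hazard / cumulative hazard / survival and
  exact cumulative-hazard inversion for piecewise baselines
  (`baseline_hazard`, `cumulative_hazard`, `survival_prob`,
  `invert_cumulative_hazard`);
* **inference** — exact-event-time maximum likelihood, OFV (−2·log L),
  likelihood-ratio tests, finite-difference covariance, RSE%
  (`fit_mle`, `ofv`, `lrt`);
* **covariate search** — univariate screen plus stepwise forward inclusion
  (ΔOFV > 3.84, p < 0.05) / backward elimination (ΔOFV ≥ 6.63, p < 0.01)
  with a full audit trace (`run_scm`, `scm_config`);
* **synthetic cohorts** — registry-like simulation via inverse-transform
  event sampling with independent RNG streams
  (`simulation_config`, `generate_cohort`);
* **validation** — Kaplan–Meier estimation, simulation-based KM visual
  predictive checks, sampling-importance-resampling uncertainty
  (`km_estimate`, `vpc`, `sir`, `rse_report`);
* **reporting** — hazard ratios, hazard half-lives (`ln2/|β|`), risk-group
  survival curves, baseline-family OFV comparison, and an end-to-end demo
  pipeline (`hazard_ratio`, `half_life`, `risk_group_curves`,
  `compare_baselines`, `run_demo`).

## A worked example

Simulate a registry-like cohort (7,697 subjects, 7.37-year uniform-entry
censoring window, registry covariate prevalences) from a decaying two-phase
Gompertz truth, then refit it:

```r
library(recurtte)

truth <- stroke_model(levels = c(0.08, 0.02), shapes = c(-1.63, -0.23))
cfg   <- simulation_config(7697, model = truth,
                           prevalences = stroke_prevalences(), seed = 1)
coh   <- generate_cohort(cfg)
summarize_cohort(coh)
#> Cohort: 7697 subjects, 532 events (6.91%)
#> Median time to event: 0.288 years (events only)
#> Maximum follow-up: 7.37 years
#> Covariate prevalence (overall / event / no event):
#>   HPLD: 0.268 / 0.444 / 0.255
#>   IHD: 0.113 / 0.226 / 0.105
#>   HTN: 0.708 / 0.833 / 0.699
#>   APLT: 0.892 / 0.823 / 0.897

fit <- fit_mle(coh, truth)
fit
#> Hazard-model fit: OFV = 4053.6772 (converged), 7697 subjects / 532 events
#>   th1            0.088253  (RSE 15.7%)
#>   th3            0.022154  (RSE 26.5%)
#>   th2             -1.6997  (RSE 11.7%)
#>   th4             -0.2638  (RSE 20.9%)
#>   HPLD            0.83502  (RSE 10.5%)
#>   IHD             0.88276  (RSE 11.8%)
#>   HTN             0.76384  (RSE 15.2%)
#>   APLT           -0.59827  (RSE 19.0%)
```

The four baseline parameters (`th1`, `th3` scales; `th2`, `th4` shapes) and
all four covariate coefficients land close to the generating values
(0.08 / 0.02 / −1.63 / −0.23 and 0.799 / 0.745 / 0.711 / −0.514). The
derived clinical quantities are closed forms:

```r
hazard_ratio(c(0.799, 0.745, 0.711, -0.514))
#> 2.223 2.106 2.036 0.598     # HRs of HPLD, IHD, HTN, APLT
half_life(1.63)
#> 0.4252 years  (hazard halves/doubles every ~5.1 months)
```

`run_scm()` then performs the stepwise covariate search, `vpc()` checks the
final model against the observed Kaplan–Meier curve, and `sir()` replaces
Wald intervals with sampling-importance-resampling percentiles. The whole
chain is available as `run_demo(out_dir, seed)`, which writes the cohort,
fit JSONs, SCM trace, VPC bands, SIR report and a reproducibility manifest.

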