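# doseflow

Bayesian dose finding and remote hemodynamic monitoring analysis for
small adaptive tolerability trials — the setting where a repurposed drug
is titrated in a dozen-patient pulmonary arterial hypertension (PAH)
cohort while implanted pulmonary-artery pressure sensors stream daily
hemodynamics.

The package has three connected parts:

1. **Dose finding.** A one-parameter power-model continual reassessment
   method (CRM): the probability of a dose-limiting tolerability event at
   standardized dose *d* is modelled as

   *p*(tox | *d*) = *d*<sup>α</sup>,  α ~ Gamma(1, 1),

   with the skeleton *d₁ < … < d_K* carrying the prior toxicity guesses.
   Posterior means *E*[*d*<sup>α</sup> | data] are computed by adaptive
   quadrature over α; each new patient is assigned the dose whose
   posterior mean toxicity is closest to the 20% target (ties to the
   lower dose). `replay_trial()` reruns a recorded trial;
   `simulate_trial()`, `operating_characteristics()` and
   `sample_size_curve()` quantify the design's accuracy under assumed
   true dose–toxicity curves.

2. **Remote hemodynamics.** Daily device series are reduced to total
   pulmonary resistance (TPR = mPAP/CO, Wood units), total systemic
   resistance and wedge-imputed PVR; smoothed with trailing 3-day
   averages on a calendar grid; baseline-adjusted per patient and
   aggregated into cohort mean ± 95% CI curves; scanned for the
   stability event (≥ 6 of 7 consecutive daily TPR changes < 0.15 WU,
   summarized by Kaplan–Meier medians) and for post-withdrawal alerts
   (smoothed mPAP ≥ 110% of baseline); and summarized with paired
   endpoint statistics and exposure–response rank correlations.

3. **Synthetic cohorts.** `generate_cohort()` builds fully reproducible
   cohorts with dose-proportional log-normal exposure, a saturating
   exposure–effect link (typical 200 mg patient: 20.3% steady-state TPR
   reduction), mono-exponential onset (τ = 9 d) and slower offset
   (τ = 15 d), device noise and missing days — so the whole pipeline is
   testable end-to-end and its estimators can be checked against known
   truth.

See `vignettes/doseflow-methods.Rmd` for the full model description,
parameter defaults with units, and design rationale.

## Worked example

Thirteen serially enrolled patients, a 4-level grid, three tolerability
events — what does the model believe, and what dose comes next?

```r
library(doseflow)
model <- crm_model(dose_mg = c(100, 200, 300, 400),
                   skeleton = c(0.05, 0.10, 0.20, 0.35), target = 0.20)
obs <- tox_obs(dose_index = c(1, 2, 3, 4, 4, 3, 3, 3, 3, 3, 3, 3, 3),
               dlt        = c(0, 0, 0, 1, 1, 0, 0, 0, 0, 1, 0, 0, 0),
               model = model)
posterior_summaries(model, obs)
#> CRM posterior after 13 patients (3 DLTs)
#>  index label_mg standardized_dose mean_tox median_tox
#>      1      100              0.05    0.073      0.055
#>      2      200              0.10    0.126      0.107
#>      3      300              0.20    0.224      0.210
#>      4      400              0.35    0.366      0.361
#> alpha: mean 1.016, median 0.970
#> recommended dose: level 3 (300 mg)
```

The posterior mean toxicity at 300 mg (0.224) is the closest to the 20%
target, so level 3 is recommended for the next patient; 400 mg, with two
events in two patients, is estimated well above target.

A synthetic 13-patient instrumented cohort, all on 200 mg, analyzed by
the monitoring pipeline:

```r
coh <- generate_cohort(sim_cohort_config(fixed_dose_mg = 200, seed = 42))
curve <- cohort_curve(coh$series, "tpr", align = "start", mode = "percent")
curve[curve$rel_day %in% c(14, 28, 56), ]
#>    rel_day      mean     ci_lo     ci_hi  n
#> 44      14 -15.83104 -16.95604 -14.70604 13
#> 58      28 -19.73516 -21.04543 -18.42490 13
#> 86      56 -21.05967 -22.67175 -19.44759 13

stab <- lapply(coh$series, patient_stability, phase = "onset")
km <- km_summary(sapply(stab, `[[`, "time"), sapply(stab, `[[`, "event"))
#> median time to TPR stability: 20 days (95% CI 16-23)
```

The cohort TPR falls about 16% by day 14 and levels off near −21% — the
95% interval at day 56 covers the generator's true 20.3% steady-state
reduction — and the 6-of-7/0.15-WU detector dates stability at a median
of 20 days on drug.

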