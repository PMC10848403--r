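# lfrecur

Recurrent liver-function event analysis after hepatic radiotherapy.

Long-term liver function in hepatocellular-carcinoma patients treated
with hepatic radiotherapy fluctuates: the six routine chemistries —
bilirubin (BIL), AST, ALT, alkaline phosphatase (ALKP), INR, albumin
(ALB) — rise and fall over years of follow-up, and a patient can
deteriorate repeatedly. `lfrecur` is for biostatisticians and outcomes
researchers who want to treat those fluctuations as **recurrent
time-to-event data**: it grades each lab value on a CTCAE-style ladder,
declares an event whenever a grade exceeds its running comparator,
fuses same-day events across chemistries into combined events, lays the
follow-up out as Andersen–Gill counting-process intervals, and fits an
extended Cox model.

The intensity model for patient *i* is

    lambda_i(t) = lambda_0(t) * exp( x_i' beta + (x_i,td' beta_td) * t )

with `t` in months since radiotherapy completion. Estimation is by
partial likelihood (Efron or Breslow ties) over risk sets
`{j : start_j < t <= stop_j}`; covariate-by-time products are evaluated
exactly at event times. Inference uses the cluster-robust sandwich
`V (Σ_g U_g U_g') V` with patients as clusters, so the within-patient
correlation of recurrent events is accounted for. Proportional hazards
is tested per term on scaled Schoenfeld residuals (Grambsch–Therneau);
terms that violate PH *and* have significant main effects receive
`x * t` products in a second-stage extended fit, and
`hr_at_time(fit, term, t) = exp(beta_main + beta_td * t)` traces the
resulting time-varying hazard ratio.

A two-tier synthetic-cohort generator (exact event times by
Lewis–Shedler thinning; full fluctuating lab trajectories with an exact
grade round-trip) provides ground truth for calibration and recovery
studies.

## Worked example

The numbered scripts under `analysis/` run a full study on a simulated
133-patient cohort:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_derive_events.R
Rscript analysis/03_fit_models.R
Rscript analysis/04_sensitivity.R
```

`01` writes the cohort (`results/cohort/`): 133 patients, ~8,000 lab
records, baseline ALL6 scores 0–9. `02` derives the events:

```
719 individual events -> 541 combined ALL6 events over 1503.0 person-months
combined-event incidence: 0.36 per person-month
```

and shows the incidence rising with baseline score (0.36 per
person-month at score 0 to 0.53 at score 9 in this cohort). `03` fits
the nine-covariate PH model, tests PH, and extends where warranted:

```
Counting-process Cox fit (efron ties): 541 events / 607 intervals / 123 patients
           term     coef    hr robust_se ci95_low ci95_high        p
 baseline_score  0.08580 1.090   0.01490    1.060     1.120 8.08e-09
      age_group -0.05380 0.948   0.02690    0.899     0.999 4.55e-02
         female  0.15700 1.170   0.05580    1.050     1.300 5.00e-03
 ...
```

Here the baseline score carries a hazard ratio of 1.09 per unit (robust
95% CI 1.06–1.12): each additional grade of pre-treatment liver
dysfunction raises the deterioration intensity by ~9%. (The estimate is
attenuated relative to the generating 1.17 because events are only
observed at visits — see the vignette.) Ten of 133 patients dropped out
before their first follow-up visit and contribute no risk time. In this
replicate no term met the two-condition PH-extension rule, so the
extended model equals the PH model; the test suite exercises cohorts
where the gender-by-time term is detected and recovered. `04` repeats
the analysis for cutoff scale factors 0.7–1.3 and for the ALL4/ALL3
composite substitutions (the score effect stays positive: HR 1.09 →
1.14 → 1.20 as the composite narrows).

Programmatic use mirrors the scripts:

```r
library(lfrecur)
cfg <- run_config(sim_spec = cohort_spec(n_patients = 133), seed = 1)
report <- run_pipeline(cfg)
print(report)
```

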