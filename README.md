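# gmftwin

Generalized metabolic flux digital twins for chronic kidney disease (CKD)
risk in type 2 diabetes.

Routine diabetes care collects a small panel of biomarkers — fasting
glucose, lipids, serum creatinine, BMI, HbA1c, hemoglobin, systolic blood
pressure, sometimes ACR or a liver panel — while the dedicated kidney
markers (ACR, eGFR) are often missing or unreliable for prognosis.
`gmftwin` turns that sparse panel into a *digital twin*: a per-patient
vector of relative metabolic pathway rates (generalized metabolic fluxes)
over a declarative species/flux network, estimated by best fit and usable
for CKD identification, multi-year prediction, risk stratification and
progression analysis.

The core model is log-linear quasi-steady state.  With incidence matrix
`A` (+1 producing, −1 consuming) and log biomarker deviations
`y = log(x / reference)`, fluxes solve the ridge-regularized inverse
problem

    û = argmin ‖W^½ (y_obs − A_obs u)‖² + λ‖u‖²,   λ = 0.1 by default,

over the rows where the biomarker is *present* — missing biomarkers are
dropped rows, never imputed.  Relative fluxes `g = exp(û)` (population
reference = 1) feed:

* **Risk modelling** — logistic regression on fluxes + age + gender, rank
  AUC with out-of-bag bootstrap intervals, balanced 50/25/25 splits,
  significant-predictor tables and top-k ablations;
* **Stratification** — low / moderate / high bands (<10%, 10–30%, >30%
  predicted risk) with observed-versus-expected event rates;
* **Profiles** — Kendall τ input–flux correlation maps, subgroup and
  SGLT2-inhibitor flux-profile comparisons (Wilcoxon–Mann–Whitney);
* **Progression** — Kaplan–Meier / log-rank / Cox by risk group, 3/5/10-year
  horizon labels, k-means clustering with BSS-based model selection and
  cluster-distance-versus-outcome analysis;
* **Simulation** — a ground-truth synthetic cohort generator (latent
  disease severity, planted flux effects, survival outcomes, datamart-style
  missingness) for end-to-end recovery testing.

Everything is tidyverse-shaped: cohorts and results are tibbles, fitted
objects have `tidy()` / `glance()` methods, result types have `autoplot()`
or `plot_*()` companions.

## Worked example

```r
library(gmftwin)

sim <- simulate_cohort(cohort_spec(n = 1000), seed = 42)
net <- gmf_network("incomplete-11")     # the 11-biomarker datamart panel
net
#> <gmf_network> input set 'incomplete-11'
#>   species:    20 (11 observable under this set)
#>   fluxes:     21 (21 informative)

profiles <- fit_gmf(sim$cohort, net)
labels   <- horizon_labels(sim$cohort, horizon = 3)
refs     <- calibrate_references(profiles, labels$label)
profiles <- add_extent(profiles, refs)
profiles[1:3, c("patient_id", "n_observed", "extent", "Ex.HbA1c → ACR")]
#>   patient_id n_observed extent `Ex.HbA1c → ACR`
#> 1 p00001             10  2.89             1.07
#> 2 p00002             11  3.19             1.07
#> 3 p00003              9 -0.672            0.957
```

Each row is one patient: `n_observed` biomarkers survived the missingness,
`extent` places the patient on the axis between the median non-CKD state
(0) and the median CKD state (1) — patient 3 sits healthier than the
non-CKD median, patients 1–2 far beyond the CKD median — and each flux
column is a relative pathway rate (1 = population reference; 1.07 means
the HbA1c-to-ACR spill-over runs 7% above reference).

```r
features <- gmf_features(profiles, sim$cohort, labels$label)
model    <- fit_ckd_lr(features)
significant_predictors(model)
#>   predictor           estimate    p.value
#> 1 Ex.HbA1c → ACR          7.66 0.00000762
#> 2 Cholesterol → HDL      -2.92 0.00116
#> 3 intake → Glucose        6.96 0.00315
#> 4 muscle → Creatinine     3.62 0.00878

bootstrap_auc(features, B = 200, seed = 1)
#> <auc_report> AUC 0.811 (bootstrap median 0.796, CI 0.757-0.836,
#>              B = 200/200, out_of_bag_refit)

risk <- predict_risk(model, features)$.risk
risk_outcome_table(assign_risk_group(risk), features$label)
#>   risk_group n_no_ckd n_ckd pct_ckd expected_median_pct within_expected
#> 1        low      197    10     4.8                   5            TRUE
#> 2   moderate      300    74    19.8                  20            TRUE
#> 3       high      184   235    56.1                  65            TRUE

cox_hr(sim$cohort$followup_years, sim$cohort$ckd_event,
       assign_risk_group(risk) == "high")
#>      hr ci_lower ci_upper      p.value
#> 1  5.09     4.10     6.32     3.5e-49
```

The out-of-bag AUC of ~0.80 says the flux twin separates patients who will
develop CKD within 3 years from those who will not; the band table shows
observed event rates falling inside every expected band interval (4.8% in
low, 19.8% in moderate, 56.1% in high); and high-risk patients progress to
CKD about five times faster than the rest.

`run_gmf_pipeline()` chains all stages (simulate/read → fit → train →
stratify → profiles → survival → clusters) into a directory of CSV outputs
with a JSON manifest.

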