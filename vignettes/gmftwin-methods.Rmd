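---
title: "Metabolic flux digital twins for kidney risk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic flux digital twins for kidney risk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmftwin)
```

## The problem

Chronic kidney disease (CKD) in type 2 diabetes is usually detected through
two dedicated markers — the urinary albumin-to-creatinine ratio (ACR) and the
estimated glomerular filtration rate (eGFR).  Both are often missing from
routine records, and neither is a reliable prognostic signal on its own.
`gmftwin` takes a different route: it summarizes a patient's *whole*
metabolic state as a vector of relative pathway rates — generalized
metabolic fluxes — estimated by best fit from the ten to fourteen cheap
biomarkers that routine diabetes care already collects (fasting glucose,
lipid panel, serum creatinine, BMI, HbA1c, hemoglobin, systolic blood
pressure, and optionally ACR, serum albumin, ALT, AST and hematocrit).
That per-patient flux vector, the *digital twin*, then drives CKD
identification, 3-to-10-year prediction, risk stratification, profile
characterization and progression-rate analysis.

## The flux network and forward model

The shipped network (`gmf_network()`, defined in
`inst/extdata/gmf_network.yaml`) declares 20 species — 15 observable through
a biomarker, 5 latent (reactive oxygen metabolites, an excreted-HbA1c pool,
a circulation pool, stored fat lipids and free fatty acids) — connected by
21 informative fluxes spanning glucose metabolism, ROS/HbA1c production,
respiration-circulation, blood pressure, lipid metabolism,
kidney-creatinine handling and albumin-ACR handling.  The signed incidence
matrix $A$ (species $\times$ fluxes) holds $+1$ where a flux produces a
species and $-1$ where it consumes it; a reversible flux is a single signed
column.

The observable model is **log-linear quasi-steady state**.  Writing $u_j$
for the log deviation of flux $j$ from its population reference and $y_i =
\log(x_i / \mathrm{ref}_i)$ for the log deviation of biomarker $i$,

$$y = A_{\mathrm{obs}}\, u ,$$

where $A_{\mathrm{obs}}$ restricts $A$ to the observable species of the
active input set.  The reading is that concentrations sit where production
and consumption balance, so a sustained shift in the balance of rates moves
the log concentration by the signed sum of the log rate shifts.  This is a
deliberate simplification — it has no dynamics, no saturation, and no
thermodynamic constraints — chosen because it makes the inverse problem a
regularized linear least squares with a closed form, and therefore makes
every downstream claim exactly testable.

Two structural choices deserve a note.  The lipid pathway is entered from
glucose (`"Glucose → Fat-lipids"`, de-novo lipogenesis) rather than from an
external intake pool, which keeps the species graph connected — a validated
invariant.  And the renal clearance flux `"Creatinine → excretion"` also
consumes ACR, because urinary creatinine is the denominator of the
albumin-to-creatinine ratio; this couples the kidney and albumin-ACR
pathway groups.

## The inverse problem

`fit_gmf()` estimates each patient's fluxes by ridge-regularized weighted
least squares over the *present* biomarkers only:

$$\hat u = \arg\min_u \; \lVert W^{1/2}(y_{\mathrm{obs}} - A_{\mathrm{obs}}
u)\rVert^2 + \lambda \lVert u \rVert^2 .$$

Missing biomarkers are dropped rows — never imputed — so the estimator for
a patient with a sparse panel is *exactly* the estimator one would get had
those biomarkers never been measured.  With at most 14 observations
informing 21 fluxes the problem is underdetermined; the ridge term (default
$\lambda = 0.1$, mild) selects the solution closest to the population
reference ($u = 0$, all relative fluxes $g_j = e^{u_j} = 1$).  At $\lambda =
0$ the minimum-norm least-squares solution is returned via the SVD
pseudoinverse.  Residual weights default to 1: the log transform already
puts biomarkers on comparable scales.  A patient with an empty panel
collapses to the population reference and is flagged.

**Structural identifiability.**  A consequence of the closed form is worth
stating precisely, because it shapes the inference downstream.  By the
push-through identity, $\hat u_j = a_j^\top (A_p A_p^\top + \lambda
I)^{-1} y_p$, where $a_j$ is flux $j$'s column restricted to the present
rows.  Any linear dependence among the *full* observable columns therefore
makes the corresponding fitted fluxes exactly collinear for every patient
and every missingness pattern.  Under the 11-biomarker input set only 11 of
the 21 fluxes are structurally identifiable (`identifiable_fluxes()`), and
the logistic model below excludes the aliased ones from coefficient
inference rather than leaving the aliasing to the regression's internal QR
factorization, whose tolerance-dependent column drops would make Wald
p-values arbitrary.

## Reference states and the generalized extent

Two reference health states anchor a one-dimensional progression scale:
state A (diabetes without CKD) and state B (diabetes with CKD), each
defined as the component-wise median log flux vector of the corresponding
labelled patients (`calibrate_references()`).  A patient's **generalized
extent** is the scalar projection of their flux deviation onto the A-to-B
axis,

$$\mathrm{extent} = \frac{(u - u_A)\cdot d}{\lVert d \rVert^2},
\qquad d = u_B - u_A,$$

so a patient at state A scores 0, at state B scores 1, and values outside
$[0,1]$ are reported unclipped — a patient can be healthier than the median
non-CKD patient or further progressed than the median CKD patient.

## Risk modelling

`fit_ckd_lr()` is plain maximum-likelihood logistic regression (IRLS via
`stats::glm()`) of a CKD label on the identifiable relative fluxes, age
(z-scored on the training data) and gender (female 0, male 1), with Wald
p-values from the observed information.  Discrimination is summarized by
the Mann-Whitney rank AUC; `bootstrap_auc()` reports the median and
2.5-97.5 percentile interval of out-of-bag AUCs across `B = 2000` (default)
resample-refit iterations.  The out-of-bag scheme was chosen over
rescoring-only because refitting inside every resample is the honest
variance estimate for a model developed and assessed on a single cohort;
`scheme = "resample_test"` serves the dedicated-split design.  The interval
is a percentile interval rather than a min-max range so its width does not
grow with `B`.  Operating-point metrics default to the threshold maximizing
Youden's J on the training data.  `balanced_split()` redraws a 50/25/25
partition until age (Kruskal-Wallis), gender and hypertension (chi-square)
show no significant imbalance at p > 0.05; hypertension means a positive
flag or SBP $\ge$ 140 mmHg.

Predicted probabilities stratify into three bands — low below 0.10, high
above 0.30, moderate between, boundaries assigned to moderate — with
expected median event percentages 5/20/65 and expected intervals <10%,
10-30%, >30% used to flag each band's observed rate
(`risk_outcome_table()`).

## Clinical labels

eGFR is computed by a configurable piecewise power law; the shipped
coefficient set is CKD-EPI 2009 with the race term off by default.  Sites
using locally modified equations (several Asian variants circulate whose
exact coefficients are not always published) can supply their own
coefficient sets via `egfr_coefficients()`; hard-coding an uncertain
variant was deliberately avoided.  CKD positivity is ACR strictly above
3.3 mg/mmol (30 mg/g) or eGFR strictly below 60 mL/min/1.73 m²; boundary
values are negative, and with ACR missing only the eGFR clause applies.
Repeated measurements aggregate to a baseline panel by the per-biomarker
median over the year before baseline; a biomarker with no in-window
measurement is missing.

## Profiles, survival and clustering

`input_flux_correlation()` computes tie-corrected Kendall $\tau_b$ between
inputs and fitted fluxes (clinical columns tie heavily, so the tie-corrected
variant is the right one), with cohort-median substitution for missing
inputs, z-score normalization, and complete-linkage hierarchical ordering
of the heatmap.  `subgroup_profile()` compares groups per flux by the ratio
of medians with a two-sided Wilcoxon-Mann-Whitney test; fluxes are called
elevated/reduced at p < 0.05 with no multiplicity adjustment — the
convention of these profile maps — which the documentation flags as a known
limitation for borderline calls.  `sglt2i_analysis()` applies the same
comparison to medicated versus unmedicated patients within each
future-outcome stratum.

Time-to-event analysis wraps the `survival` package: Kaplan-Meier
product-limit curves, the log-rank test, and a Cox proportional-hazards
ratio (Efron ties) for high-risk versus moderate/low-risk patients.
Event-free subjects with follow-up shorter than a prediction horizon are
excluded from horizon classification but retained, censored, for the
survival analyses — an explicit convention choice.

`kmeans_bss()` z-scores its columns and picks the smallest $k \in [5, 20]$
whose between-sum-of-squares fraction reaches 50% (ten restarts per $k$,
all seeded); smallest-k-reaching-target was preferred over
nearest-to-target as the more conservative reading.
`cluster_distance_outcome()` orders clusters by ascending event rate
(ties broken by size), measures Euclidean centroid distance from the
lowest-rate cluster, and correlates distance with rate by Kendall's
$\tau$.

## The synthetic cohort generator

No real cohort ships with the package, so `simulate_cohort()` defines the
study conditions.  One latent severity $s \sim \mathrm{Beta}(2, 5)$ drives
everything: true fluxes $u = (s - \bar s)\,d_{\mathrm{true}} +
\varepsilon_{\mathrm{flux}}$ with flux noise 0.05 log units; observables
$x = \mathrm{ref}\cdot\exp(A_{\mathrm{obs}} u + \varepsilon)$ with
observation noise 0.1 log units; CKD event times exponential with hazard
$\propto e^{7s}$, scaled so the 3-year event probability is 0.34, censored
uniformly on (3, 6) years.  Reference levels and marginal targets are the
means typical of a tertiary-care diabetes datamart (HbA1c 8.0%, SBP 133.8
mmHg, creatinine 74 µmol/L, ...).  Age is truncated normal 57 (12.4) on
[20, 80] and tied to severity by a Gaussian copula ($\rho = 0.35$,
marginals preserved) — older patients carry more disease, which is why age
is a genuinely informative covariate here.  SGLT2 inhibitor use (prevalence
0.15) shifts the lipid fluxes ($+0.2$ on lipolysis, $-0.2$ on fat
deposition).  The default missingness is the datamart pattern: serum
albumin, ALT, AST and hematocrit absent entirely, the remaining eleven
biomarkers masked completely at random at rate 0.15.

Two centring choices keep the generator self-consistent.  The severity
effect is applied as $(s - \bar s) d_{\mathrm{true}}$, and each biomarker's
log-normal mean bias is corrected analytically (exact Beta and Bernoulli
moment integrals), so marginal means match their configured targets
exactly in expectation — without this, the planted disease signal would
drag every marginal away from its target.

$d_{\mathrm{true}}$ places its largest components on the two fluxes
`"Ex.HbA1c → ACR"` (+1.10) and `"Hb.ROM → HbA1c"` (+1.00) — glycation
products spilling into urine and oxidative glycation of hemoglobin — with
milder involvement of glucose intake/utilization, blood-pressure drive,
lipid turnover, creatinine retention and depressed albumin handling.
Spreading the signal across pathways is deliberate: severity is then
recoverable from many complementary biomarkers, the way real multi-system
deterioration presents, and removing any small predictor subset degrades
but does not destroy the model, while *keeping only* the top predictors
discards the noise-averaging benefit of the rest.

**What passing tests do and do not show.**  The generator is a clean
single-factor world: every biomarker is an undistorted log-linear image of
one severity axis plus isotropic noise.  Real cohorts are not like this —
they carry multi-factor confounding, heteroscedastic assay noise, and
informative missingness, none of which the generator emulates.  Recovery
results on this generator therefore demonstrate the correctness of the
machinery, not field performance.  One concrete consequence: k-means on the
raw biomarker panel aligns with outcome rates at least as well as k-means
on fitted fluxes here, because the raw panel is itself a noiseless-enough
view of the single axis; the practical advantage of twin-space clustering
on real data rests on raw-input confounding this generator does not
contain.

## Numerical choices and degenerate inputs

Fits use the Cholesky solve of the $21\times 21$ ridge normal equations
(patients grouped by missingness pattern, multi-right-hand-side), or the
SVD pseudoinverse at $\lambda = 0$ with singular values below
$10^{-10}\sigma_{\max}$ treated as zero.  Closed-form agreement with an
independent SVD oracle is held to $10^{-8}$.  Constant columns in
correlation analyses yield $\tau = 0$ with a flag rather than `NA`
propagation.  Empty risk bands report `n = 0` with an undefined
percentage.  A Cox arm without events is reported with its unbounded
estimate and a flag, never silently.  Exact ties in cluster event rates
are broken by cluster size, larger first, and logged in the ordering.

## Problem sizes used in the checks

The shipped tests run the full recovery analyses at the generator's default
scale ($n = 2000$) across dozens of seeds, with bootstrap sizes reduced
from the 2000-iteration default (to 80–500) where the quantity being
checked is an ordering or a coverage property rather than an interval
width; `scripts/acceptance.R` reports the default-scale quantities for a
single seed with `B = 500`.

## Known limitations

Single-time-point fitting only — longitudinal multi-visit twins are out of
scope.  The forward model is linear in log space; strongly nonlinear
regulation (e.g. saturating clearance) is outside its expressiveness.  The
significance conventions in profile maps are unadjusted for multiplicity.
The eGFR default is the 2009 equation; coefficient sets in local clinical
use should be supplied explicitly.  The generator's realism limits are
described above.
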