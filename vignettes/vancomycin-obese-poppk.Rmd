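---
title: "Methods: vancomycin population PK and dose individualization in obese adults"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vancomycin population PK and dose individualization in obese adults}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vancopk)
```

## The problem

Vancomycin is dosed against an exposure target: a 24-h area under the
concentration–time curve (AUC₂₄) of 400–600 mg·h/L at an assumed MIC of
1 mg/L. In obese adults (BMI ≥ 30 kg/m²) neither total body weight nor
standard renal formulas describe the drug's disposition well, and the
clinically critical window is the *first days* of therapy, before
measured levels can guide adjustment. `vancopk` implements the full
analysis chain for this setting: covariate derivation, a population PK
model, estimation from sparse therapeutic-drug-monitoring (TDM) data,
simulation-based model diagnostics, and Monte Carlo evaluation and
optimization of initial dosing regimens.

## Model

### Structural and statistical model

Concentrations follow a one-compartment model with first-order
elimination under zero-order infusions. For an infusion of rate $R$
(mg/h) and duration $D$, with elimination rate constant
$k_e = CL/V_d$, the contribution at elapsed time $\tau$ is

$$
C(\tau) \;=\;
\begin{cases}
\dfrac{R}{CL}\left(1 - e^{-k_e \tau}\right), & \tau \le D,\\[6pt]
\dfrac{R}{CL}\left(1 - e^{-k_e D}\right) e^{-k_e (\tau - D)}, & \tau > D,
\end{cases}
$$

and a regimen is the superposition of its events. The window AUC is
computed from exact mass balance,
$AUC_{0..t} = (\text{input}(t) - V_d\,C(t))/CL$, so no numerical
integration enters anywhere in the pipeline. A one-compartment structure
slightly misstates the brief distribution phase; because distribution
contributes little to total vancomycin exposure and sampling rarely
catches it, the simplification has no practical impact on AUC-targeted
dosing.

Between-subject variability is lognormal on both parameters,

$$
V_{d,i} = V_{d,pop}\, e^{\eta_{V,i}}, \qquad
CL_i = CL_{pop}\, e^{\beta_{eGFR}\,eGFR_i}\, e^{\beta_{LBM}\,LBM_i}\,
e^{\eta_{C,i}},
$$

with $\eta \sim N(0, \Omega^2)$ independent per parameter, and the
residual error is additive Gaussian with constant SD $\sigma$ (mg/L).
The covariate model is deliberately *uncentered*: $CL_{pop}$ is the
typical clearance at eGFR = 0 and LBM = 0, which is how the shipped
coefficients are defined (`published_params()`); `typical_cl(1.51, 68, pop)`
therefore evaluates to ≈ 7 L/h, and with $V_d$ = 75 L the half-life
$0.693\,V_d/CL$ is ≈ 7.4 h.

### Parameters and units

| parameter | unit | shipped value | meaning |
|---|---|---|---|
| `vd_pop` | L | 75.0 | typical volume of distribution (no covariate found) |
| `cl_pop` | L/h | 1.32 | typical clearance at zero covariates |
| `beta_cl["EGFR"]` | (mL/s/1.73 m²)⁻¹ | 0.61 | exponential eGFR effect on CL |
| `beta_cl["LBM"]` | kg⁻¹ | 0.011 | exponential lean-body-mass effect on CL |
| `omega_vd`, `omega_cl` | – | 0.31, 0.28 | SDs of the lognormal random effects |
| `sigma_add` | mg/L | 2.9 | additive residual SD |

Renal function uses the CKD-EPI equations (2009 creatinine; 2012
cystatin-C-only), with creatinine in µmol/L (converted internally by
88.4) and output in mL/s/1.73 m² — the unit in which the eGFR
coefficient is expressed. The 2009 creatinine equation was chosen over
the 2021 race-free refit because the model's coefficient was estimated
against it; the race factor defaults to 1 and is configurable. Body size
uses the Du Bois BSA and Boer LBM formulas (height in metres, converted
to cm internally). Cockcroft–Gault is deliberately not provided: it
contains total body weight and overestimates clearance in obesity.

## Estimation

The marginal likelihood integrates the two random effects out of each
patient's contribution. The integral is approximated around the
conditional mode $\hat\eta_i$ (found by a damped Gauss–Newton iteration
with analytic first and second derivatives of the infusion model) either
by the Laplace method or, the fitting default, by 5×5-node adaptive
Gauss–Hermite (AGH) quadrature. On sparse one-to-two-sample designs with
additive error the Laplace approximation carries a small per-subject
error, so AGH — which agrees with dense brute-force quadrature to a few
hundredths of an OFV point per subject in the test suite — is used for
all model fitting; Laplace remains available and is itself verified
against the same oracle.

Numerical choices that matter:

* **Deterministic inner problem.** Conditional modes are re-solved from
  the prior mode ($\eta = 0$) at every objective evaluation. Warm starts
  across outer iterations were measurably faster but allowed the inner
  solver to hop between basins of occasionally multimodal conditional
  posteriors, which made the outer objective path-dependent and stalled
  the optimizer; determinism was preferred over the speed.
* **Quadrature scaling.** The AGH transform is scaled by the
  Gauss–Newton (rather than exact) Hessian at the mode. The exact
  Hessian can become near-singular for single subjects in unremarkable
  parameter regions, and its log-determinant then acts as a needle the
  outer optimizer exploits; the Gauss–Newton matrix is positive definite
  with determinant bounded below by the prior precision, and the 25-node
  sum absorbs the scaling crudeness.
* **Outer optimization.** Population parameters are optimized on the log
  scale (covariate coefficients unconstrained) by `nlminb` with explicit
  central-difference gradients (step 10⁻⁵) and restart polishing until
  the OFV is stable to 10⁻³; covariates are centered at their cohort
  means during optimization (and transformed back for reporting) because
  the uncentered parametrization makes $CL_{pop}$ and the coefficients
  nearly collinear.
* **Standard errors.** Relative standard errors come from the inverse
  central-difference Hessian of the OFV (step 0.01 on the optimization
  scale — wide enough to average over residual basin-switch kinks), with
  the delta method back to natural scale. When the Hessian is not
  positive definite (sparse designs can leave a near-flat ridge), RSEs
  are reported as `NA` rather than pseudo-inverted; the bootstrap is the
  fallback uncertainty estimate.

Covariate model building follows standard stepwise testing: Pearson
screening of log-scale empirical-Bayes estimates against candidate
covariates (p < 0.05 to qualify), forward addition accepting the largest
OFV drop above 3.84 (χ², 1 df, p < 0.05), backward elimination removing
covariates whose loss raises the OFV by at most 6.64 (p < 0.01). The
bootstrap resamples patients with replacement and refits the fixed final
covariate structure, reporting percentile 2.5/50/97.5 summaries.

## Synthetic cohorts

The generator emulates the structure of a real obese TDM cohort:

* **Covariates.** Sex 82:56 male:female; age truncated normal (65, SD
  back-solved from the IQR 54–72, bounds 26–86); height sex-shifted
  truncated normal (1.79/1.65 m, SD 0.08); BMI truncated lognormal whose
  meanlog/sdlog were solved so that the ≥ 30 kg/m²-truncated distribution
  reproduces the published quantiles (a naive IQR back-solve ignores the
  eligibility truncation and under-disperses); weight is **derived** as
  BMI × height², which matches the BMI and weight marginals
  simultaneously and gives the derived lean body mass its observed
  dispersion — drawing weight independently of height cannot do both.
  Serum creatinine and urea are truncated lognormals matched to their
  median/IQR/range; cystatin C is present in a third of patients.
* **Regimens.** Loading dose 1–4 g (median 2.5 g) in 122/138 patients
  over 0.5–7 h; maintenance 0.5–1.5 g (median 1 g) every 6/8/12/24 h
  over 1–3 h; ~6.5% continuous infusion 1–4 g/day. Interval and
  maintenance-dose weights shift with eGFR, mirroring renally adjusted,
  largely pharmacist-guided practice; the marginal grids and medians are
  preserved.
* **Sampling.** 84.4% troughs (0–1 h before a dose, weighted toward
  later dose occasions, as TDM troughs are drawn once therapy is
  established), 7.5% peaks (≤ 2 h after infusion end), 8.2% mid-interval;
  1–2 samples per patient within 72 h; simulated concentrations get
  additive error and are dropped outside the 4–80 mg/L assay range
  (counts kept as attributes).

What the generator does **not** emulate: diagnosis mix and pathogen MICs
beyond the fixed 1 mg/L assumption, any correlation between covariates
beyond the weight–height–sex coupling, time-varying renal function, and
adherence/recording errors. Passing tests on these cohorts therefore
demonstrate that the estimator and dosing machinery recover what they
put in under realistic sparsity — not that the published model is
correct for any particular hospital's patients.

One regime choice deserves emphasis: a real TDM dataset contains only
reportable concentrations, with no below-range samples, because dosing
is individualized to keep patients in range. Simulation experiments
that evaluate *estimation* (parameter recovery, selection calibration)
therefore run the generator without assay censoring; with censoring
active, the unmodeled M1-style dropping of ~7% of samples biases
clearance upward and inflates the null covariate-entry rate (measured
9.5% against ~3% without, at a nominal 5%). The default generator keeps
the assay limits, since exposure simulation and diagnostics should see
realistic data.

## Monte Carlo dosing evaluation

PTA is the percentage of simulated patient-replicates whose AUC₂₄ falls
in the closed interval [400, 600] mg·h/L. Exposure is scored as the mean
daily AUC over the full 60-h initial-treatment horizon,
$AUC(0\!-\!60)\times 24/60$: initial dosing is designed around the
loading-dose day, and windows that skip it (24–48 h, 36–60 h) score
systematically lower and flatten the differences between strata that the
dosing table is built to exploit. The window is an argument throughout,
so day-1 (0–24) or steady-state-like late windows are one keystroke away.

The dosing table maps eGFR strata {< 0.5, 0.5–1, 1–1.5, 1.5–2.13,
> 2.13 mL/s/1.73 m²} × LBM {< 70, ≥ 70 kg} to loading dose, maintenance
dose and interval; stratum edges are half-open, lower edge inclusive, so
eGFR 1.5 belongs to 1.5–2.13 and LBM 70 to the upper stratum. Simulation
uses 250 random-effect replicates per patient (34,500 profiles for a
138-patient cohort); the grid optimizer shares one set of draws across
candidate regimens (common random numbers) and breaks PTA ties toward
the lower total daily dose, then the lower loading dose.

## Diagnostics

PWRES standardizes each observation against the mean and SD of its
full-model simulation distribution. NPDE applies the standard
decorrelated-rank procedure (Cholesky decorrelation with the simulated
mean and covariance per patient; mid-ranks; clipping to the open unit
interval; normal quantile), falling back to marginal ranks if the
simulated covariance is singular. VPC bands are quantile-binned in time
with at least 10 observations per bin. PWRES and NPDE computed together
share one simulation stream, and every diagnostic is bit-reproducible
given (data, model, `n_sim`, seed); the default `n_sim` is 1000.

## Problem sizes in the shipped tests

The test suite exercises the pipeline at the sizes the analysis itself
uses: cohorts of 138 patients with 1–2 samples each for recovery and
dosing checks (10 seeded replicates for recovery), 50-patient cohorts ×
200 replicates for selection calibration, 40-patient cohorts × 100 seeds
for NPDE calibration, and 250 Monte Carlo replicates per patient for
PTA. These sizes keep the full suite in the minutes range while leaving
every statistical check adequately powered.

## Known limitations

* The estimator offers no censored-data (M3) likelihood; below-range
  samples are dropped, which is fine for data that contain none and
  conservative otherwise.
* Random effects are independent; a Vd–CL correlation is not estimable
  from one-to-two-sample designs and is not offered.
* The LBM coefficient sits near its identifiability limit at the study's
  sparsity: fits recover it with a relative SD around 25–30%, so
  single-cohort estimates of β_LBM should be read with the bootstrap CI
  in hand.
* The dosing table's PTA ceiling (~55–60%) is a property of the wide
  between-subject variability, not of the optimizer: with Ω_CL = 0.28 no
  fixed per-stratum regimen can place much more of the population inside
  a 1.5-fold exposure window. Individual TDM-guided adjustment after the
  first days remains essential.
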