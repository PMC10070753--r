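---
title: "Methods: a population PK pipeline for nalbuphine under general anesthesia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a population PK pipeline for nalbuphine under general anesthesia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nalbupop)
```

This vignette records the model, the estimation method, the numerical
choices and the design decisions behind `nalbupop`, in the spirit of a
methods appendix. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The hierarchical model

Plasma nalbuphine after intravenous induction dosing follows
two-compartment linear kinetics. With micro constants
$k_{10} = CL/V_1$, $k_{12} = Q/V_1$, $k_{21} = Q/V_2$ and hybrid rate
constants $\alpha > \beta > 0$ (the roots of
$s^2 + (k_{10}+k_{12}+k_{21})s + k_{10}k_{21}$), the central
concentration after a bolus dose $D$ is

$$C(t) = \frac{D}{V_1}\left[A e^{-\alpha t} + B e^{-\beta t}\right],
\qquad A = \frac{\alpha - k_{21}}{\alpha - \beta},\;
B = \frac{k_{21} - \beta}{\alpha - \beta},$$

with the standard integrated form during and after a zero-order
infusion. Doses are mg, volumes L, times h; mg/L is scaled ×1000 to
ng/mL so that 12 mg in a 32.5 L central volume reads 369 ng/mL.
Multiple doses superpose linearly (`conc_profile()`).

Between-subject variability is log-normal,
$P_i = P_{typ}(\mathrm{cov}_i)\,e^{\eta_i}$ with
$\eta \sim N(0, \Omega)$, $\Omega$ diagonal over CL, V1, Q, V2 — no
off-diagonal terms are modeled because none are reported for this drug.
Residual error is the combined model
$y_{ij} = f_{ij}(1 + \sigma_{prop}\,\varepsilon_1) +
\sigma_{add}\,\varepsilon_2$, variance
$g_{ij} = (\sigma_{prop} f_{ij})^2 + \sigma_{add}^2$.

Covariate submodels on a typical parameter $\theta_1$ with coefficient
$\theta_2$: linear $\theta_1 + \theta_2\,(c/c_{ref})$, power
$\theta_1 (c/c_{ref})^{\theta_2}$, exponential
$\theta_1 \theta_2^{c/c_{ref}}$, and categorical
$\theta_1\theta_2^{c}$ for 0/1 covariates. The linear form is applied
exactly as printed even though it does not return $\theta_1$ at the
reference covariate; its null value is $\theta_2 = 0$ while the
multiplicative forms are null at $\theta_2 = 1$ (exponential,
categorical) or $\theta_2 = 0$ (power). The shipped final model uses
the power law `Q = 245 · (HNF/617.96)^-0.58`; the reference 617.96 mL/h
is the population mean printed in the model equation (the median,
563.6, is available through the `hnf_ref` argument of
`nalbuphine_final_model()`).

## FOCE with interaction

For subject $i$ the conditional (penalized) objective is

$$l_i(\eta) = \sum_j \left[\log 2\pi g_{ij}(\eta) +
\frac{(y_{ij} - f_{ij}(\eta))^2}{g_{ij}(\eta)}\right] +
\eta^\top \Omega^{-1} \eta + \log\det 2\pi\Omega,$$

with the residual variance evaluated at $\eta$ itself — the η–ε
interaction. The inner step minimizes $l_i$ by a damped Newton search
(compiled; Fisher/Gauss–Newton curvature, backtracking line search,
quasi-Newton fallback) from zero or a warm start, giving the empirical
Bayes estimate $\hat\eta_i$. The marginal contribution is the
first-order conditional approximation: with $J$ the Jacobian of the
profile at the mode,

$$\mathrm{OFV}_i = \log\det 2\pi V_i + \tilde r_i^\top V_i^{-1}
\tilde r_i, \qquad V_i = J \Omega J^\top +
\mathrm{diag}\,g(\hat\eta_i), \quad
\tilde r_i = y_i - f(\hat\eta_i) + J\hat\eta_i.$$

Derivatives of $f$ with respect to $\eta$ use central differences
(step $10^{-4}$). This linearized form was chosen over a
Laplace-with-Fisher-curvature variant after comparing both against
adaptive Gauss–Hermite quadrature on two-random-effect toys: the
linearized objective tracked the exact marginal roughly twice as
closely (the test suite requires 0.5 OFV units; observed differences
are 0.02–0.4).

The outer problem maximizes the summed marginal likelihood over
log-transformed structural parameters, BSV variances and residual SDs
(covariate coefficients on their natural scale, log for the
positivity-constrained exponential/categorical forms), using `nlminb`
(PORT) with an explicit forward-difference gradient at step
$10^{-4}\cdot\max(|x|, 0.5)$. Inner modes are warm-started per subject
across outer iterations, which makes each evaluation cheap but leaves
a noise floor of ~1e-6 OFV units; the explicit gradient step sits well
above that floor (PORT's internal machine-precision differences would
drown small gradients in it and stall fits started near an optimum,
exactly the situation of every stepwise candidate fit). When PORT
still reports "false convergence" on the noise floor, the fit is
accepted only if probing a few steps along the steepest-descent
direction fails to improve the OFV by more than 0.5 — otherwise it is
flagged unconverged (kept, with partial results, mirroring
estimation-software practice).

The covariance step computes a central-difference Hessian of the OFV
(step $2\times10^{-3}$ on the transformed scale) with a deterministic
objective — inner modes re-solved from zero so the differences are free
of warm-start path dependence — and reports
$\mathrm{RSE}\% \approx 100\,\mathrm{SE}_{\log}$ for log-scale
parameters (50·SE on the variance log-scale for the %CV of a BSV
term). Failure downgrades the fit (RSEs become NA), never aborts.

Shrinkage is reported on the SD scale:
$\eta\text{-shr}_k = 100(1 - \mathrm{SD}(\hat\eta_k)/\omega_k)$,
$\varepsilon\text{-shr} = 100(1 - \mathrm{SD}(\mathrm{IWRES}))$.
Rows flagged `MDV = 1` (pre-dose, below-quantitation) never enter the
likelihood; no M3-style BLQ likelihood is attempted.

## Stepwise covariate modeling

The search reproduces the published two-stage procedure exactly:
covariates with more than 20% missingness are dropped; covariate
clusters with pairwise $|r| > 0.7$ (Pearson; point-biserial for
binary/continuous) are pruned to one clinically preferred member;
every remaining candidate parameter–covariate pair is screened
one-by-one against the base model at ΔOFV > 3.84; screened candidates
are then added sequentially to the running base — largest drop first,
ΔOFV > 6.63 to enter; backward elimination removes effects whose
deletion raises the OFV by ≤ 7.88, iterating to stability; finally an
effect is retained only if it moves its parameter by strictly more
than 20% across the observed 10th–90th percentile covariate range.
Each continuous pair is tested under all three continuous forms and
the best form by OFV represents the pair; binary covariates default to
the categorical form. Ties in ΔOFV break by candidate list order, so
the trace is deterministic. Candidate fits are warm-started from the
running base estimates with the new coefficient at a small non-null
value (0.05 linear, 0.1 power, 1.1 exponential/categorical) — starting
exactly at the null would strand the optimizer on a flat gradient.

## Model qualification

*Goodness of fit.* PRED is the population prediction (η = 0), IPRED
the prediction at $\hat\eta$. CWRES uses the FOCE linearization:
residuals about $f(\hat\eta) - G\hat\eta$ decorrelated by
$(G \Omega G^\top + \mathrm{diag}\,g(\hat\eta))^{-1/2}$ via a
symmetric eigendecomposition, ridge-stabilized with a warning if a
subject covariance is near-singular.

*Bootstrap.* Subjects resampled with replacement (same N,
unstratified), each replicate refitted without a covariance step;
summaries are the median and 2.5/97.5 percentiles over converged
replicates, the robustness rate $100(1 - \mathrm{failures}/n)$ and
relative bias against the original estimates.

*pcVPC.* Observations and simulated replicates are
prediction-corrected by bin,
$pcY_{ij} = Y_{ij}\,\tilde{PRED}_{bin}/PRED_{ij}$, binned on the
distinct nominal times (designs here are protocolized, so no adaptive
binning); the observed 5th/50th/95th percentiles are compared with
their simulation 95% confidence bands, and the fraction of
observations outside the pooled simulation 90% prediction interval is
reported (< 10% is the conventional acceptance rule).

*External validation.* $PE\%_j = 100(pred_j - obs_j)/obs_j$ — the
dominant pharmacometric sign/denominator convention — summarized by
MDPE (bias), MAPE
(precision) and F20/F30, against the criteria MDPE ≤ ±20%, MAPE ≤ 30%,
F20 ≥ 35%, F30 ≥ 50%. Scenario `none` predicts from the population
model; scenario `first_obs` MAP-estimates each subject's η from the
first post-dose observation only and scores the remaining
observations (the forecasting reading of "within the first
observation"; the scored subset is flagged in the result attributes).

## Simulation engine

`simulate_population()` draws η per subject and replicate, evaluates
the closed-form profile and adds combined residual error (toggleable);
negative noisy concentrations are clamped to zero and no LLOQ
censoring is applied, matching how the published summary tables reach
a minimum of 0.00. The regimen comparison runs fixed 12 mg and
0.2 mg/kg on the same virtual subjects with common random numbers —
identical η and ε streams, so the contrast is pure dose scaling — and
reports $100(\bar{C}_{perkg} - \bar{C}_{fixed})/\bar{C}_{fixed}$ at
0.05 h (early distribution), 4 h (the cohort's median operation
duration) and 12 h. Administration defaults to bolus in regimen
simulations (the published 0.05-h magnitudes are consistent with
bolus kinetics); the induction infusion (2.5 min, configurable) is
used when generating study-like datasets, since the protocol infused
15 mg over 2–3 min.

## The synthetic population

No raw clinical data are public, so the generator is a first-class
module. Each continuous covariate gets a truncated parent distribution
— normal, or log-normal for the right-skewed labs (ALT, AST, GGT,
TBIL, D-dimer, HNF), whose means sit far above their medians — with
parent parameters moment-matched so the *truncated* distribution
reproduces the published mean and SD inside the published range.
Sampling is inverse-CDF, so marginals are exact. Three dependencies are
built in: height is drawn from sex-conditional parents (−6/+7.5 cm
around the marginal mean, within-sex SD 6 cm — the observed 153–175 cm
range caps the achievable marginal SD ~11% under its target, a
deliberate fidelity-to-range choice), weight couples to height through
a Gaussian copula (ρ = 0.35), and BMI is derived as WT/(HT/100)²,
which reproduces the published collinearity findings (WT–BMI r ≈ 0.9,
sex–height r ≈ −0.7). Creatinine clearance is derived by
Cockcroft–Gault; liver class B is assigned to the highest-bilirubin
subjects at the published prevalence rather than independently, tying
the class to the labs. Binary covariates are otherwise independent
Bernoulli draws at their published prevalences.

`generate_dataset()` emits study-shaped datasets: a dose event at
time 0 (15 mg over 2.5 min by default), a flagged pre-dose row, one
observation per nominal time — the intensive 14-sample schedule
(3 min–12 h) or the sparse peri-intubation schedule, whose
unprotocolized intubation time defaults to 8 min after the start of
infusion (the induction sequence implies several minutes of drug
administration first). Combined-error draws that would produce a
negative concentration are rejected and redrawn, honoring the
non-negativity of observed concentrations; at the study's error
magnitudes this affects only the late, low-concentration samples and
shifts their mean by well under the additive SD. True η and individual
parameters ride along as an attribute so recovery tests are
self-auditing.

For small cohorts that stand in for the *specific* 27 model-building
patients (the regimen comparison reuses their weights and fluid
loads), `representative_cohort()` places each covariate at the
mid-quantiles (i−0.5)/n of its matched distribution with seeded random
pairing. An iid draw of 27 would leave the cohort mean weight with a
standard error of ~1.8 kg, and the regimen bias is driven almost
entirely by mean weight (bias ≈ 100·(0.2·W̄/12 − 1)); the quantile
construction is the synthetic analog of conditioning on the observed
cohort.

What the generator does *not* emulate: missed samples and dosing
deviations, assay error beyond the residual model, time-varying
covariates, and the unknown joint distribution of HNF with surgery
type (independence given operation duration is assumed). Passing
recovery and calibration tests therefore demonstrate correctness of
the machinery under the model's own assumptions, not robustness to
real-data violations of them.

## Problem sizes and tolerances

The replication experiments use sizes chosen to make Monte Carlo error
small relative to the tolerances while keeping a desk-scale footprint:
the simulation-recovery study fits 200 subjects × 14 observations
(well under a minute on one core with the compiled inner loops) —
large enough that structural parameters recover within a few percent;
the regimen comparison runs the full-size 1000 × 27 grid (seconds);
the null-calibration study runs 20 seeds of 20-subject, 8-sample
datasets with a single null candidate — smaller cohorts were rejected
after a calibration check: at 8 subjects the asymptotic
$\chi^2_1$ reference for ΔOFV is visibly anticonservative (null drops
past 13 OFV units were observed), a known small-sample behavior of
conditional-estimation likelihood ratios, while at 20 subjects the
null ΔOFV distribution behaves as referenced; pcVPC checks use
120-subject studies and 150 simulated replicates; the bootstrap unit
test uses 12 resamples (the study convention of 1000 is the default
argument). Closed-form kinetics are verified against adaptive ODE
integration at 1e-6 relative error; the FOCE approximation against
adaptive Gauss–Hermite quadrature at 0.5 OFV units.

## Known limitations

- Ω is diagonal; no η correlations, mixture models or SAEM-class
  estimators.
- No M3 handling of below-quantitation data beyond pre-dose flagging.
- The covariance step is a plain finite-difference Hessian; no
  sandwich estimator.
- CWRES only (no WRES/npde); VPC bins are the nominal design times.
- One- and two-compartment intravenous models only — reduced fits are
  expressed by fixing `Q` near zero rather than by a separate
  structural family.
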