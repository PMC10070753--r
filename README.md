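# nalbupop

Population pharmacokinetics of intravenous nalbuphine in adults under
general anesthesia — a complete, self-contained R implementation of the
analysis pipeline: nonlinear mixed-effects estimation, covariate model
building, model qualification and Monte Carlo dosing simulation, exercised
end-to-end on synthetic virtual cohorts that emulate the study population.

## The problem

Nalbuphine, a mixed κ-agonist/μ-antagonist opioid, is given for induction
of anesthesia either as a fixed dose or by body weight (0.2 mg/kg).
Intra-operative physiology (fluid and blood infusion, urine output) can
change drug distribution, so two questions matter clinically: which
patient factors move nalbuphine's disposition, and is weight-based dosing
worth the trouble? The package answers both with a hierarchical PK model:

- **Structural model** — two-compartment intravenous kinetics
  parameterized by clearance `CL` (L/h), central volume `V1` (L),
  intercompartmental clearance `Q` (L/h) and peripheral volume `V2` (L),
  with closed-form biexponential solutions for bolus and zero-order
  infusion input.
- **Covariate model** — hourly net fluid volume infused,
  `HNF = (FVI + BVI − UVO)/OT` (mL/h), acts on `Q` through a power law:
  `Q = 245 · (HNF/617.96)^−0.58`. Linear, power, exponential and
  categorical forms are supported for covariate testing.
- **Random effects** — log-normal between-subject variability on all four
  structural parameters (`P_i = P_typ · e^{η}`, `η ~ N(0, ω²)`), combined
  proportional + additive residual error with η–ε interaction.
- **Estimation** — first-order conditional estimation (FOCE-I): a
  compiled damped-Newton search for each subject's conditional mode η̂,
  the marginal −2·log-likelihood from the model linearized at η̂ (with
  residual variance evaluated there), and an outer quasi-Newton
  optimization on log-transformed parameters, followed by a
  finite-difference covariance step (RSEs), empirical Bayes estimates
  and shrinkage.
- **Covariate selection** — missingness screen, |r| > 0.7 collinearity
  pruning, forward screen-in at ΔOFV > 3.84, sequential forward addition
  at ΔOFV > 6.63, backward elimination at ΔOFV > 7.88, and a strict
  20%-impact retention rule.
- **Qualification** — PRED/IPRED/CWRES goodness-of-fit quantities,
  nonparametric bootstrap with robustness rate, prediction-corrected
  visual predictive checks, and external validation by PE%, MDPE, MAPE,
  F20, F30 under population-prediction and MAP-forecasting scenarios.
- **Simulation** — Monte Carlo covariate-effect profiles and a
  common-random-numbers comparison of fixed 12 mg vs 0.2 mg/kg dosing.
- **Synthetic cohorts** — virtual patients drawn from moment-matched
  truncated distributions of the study's covariate table (weight, height,
  sex, fluid balance, liver labs, ...), with derived BMI,
  Cockcroft–Gault creatinine clearance, and full synthetic PK datasets
  with ground truth attached.

## Worked example

```r
library(nalbupop)

m <- nalbuphine_final_model()
m
#> Population PK model (two-compartment IV)
#>   theta: CL=32.9, V1=32.5, Q=245, V2=83.5
#>   effect: HNF on Q (power), theta2=-0.58, ref=618
#>   BSV %CV: CL=27.7, V1=40.1, Q=17.9, V2=40.8
#>   residual: prop=0.139 (CV), add=2.88 ng/mL

# typical Q across the study's 10th/50th/90th fluid-load percentiles
sapply(c(350.1, 563.6, 973.4), function(h) typical_params(m, list(HNF = h))[["Q"]])
#> [1] 340.6369 258.4411 188.2410

# typical concentrations after the 15 mg induction infusion (2.5 min)
conc_2cmt(c(0.05, 1, 4, 12), dose = 15, tinf = 0.0417,
          CL = 32.9, V1 = 32.5, Q = 245, V2 = 83.5)
#> [1] 365.59554  86.82950  39.24700   4.69656
```

Higher fluid load lowers `Q` by the power law, but the effect on the
concentration profile is limited — the basis for the "no dose adjustment
by HNF" conclusion.

```r
# fixed 12 mg vs 0.2 mg/kg on a representative 27-patient virtual cohort
rc <- regimen_experiment(n_subjects = 27, n_replicates = 1000, seed = 5)
rc$bias
#>    time bias_pct
#> 1  0.05 5.673548
#> 2  4.00 5.500050
#> 3 12.00 5.212951
```

The weight-based arm runs ~5.5% higher on average (the cohort's mean
weight, 63.3 kg, puts the mean mg/kg dose 5.5% above 12 mg) at every
compared time — under the 6% equivalence bound, and with no reduction in
between-patient variability, supporting fixed dosing.

A full simulation-recovery study (`recovery_experiment()`) regenerates a
200-subject cohort from the final model and refits it by FOCE-I from
displaced starting values, recovering every structural parameter within a
few percent.

## Layout

| Path | Contents |
| --- | --- |
| `R/dataset_io.R` | NONMEM-style CSV dialect, event validation |
| `R/pk_model.R`, `R/covariate_model.R`, `R/pop_model.R` | closed-form kinetics, covariate submodels, model objects |
| `R/foce.R` | FOCE-I engine (inner modes, OFV, outer fit, covariance step) |
| `R/scm.R` | stepwise covariate modeling |
| `R/diagnostics.R`, `R/validation.R` | GOF, bootstrap, pcVPC, external validation |
| `R/simulate.R`, `R/experiments.R` | Monte Carlo engine, replication experiments |
| `R/synthetic.R` | virtual cohorts and synthetic datasets |
| `vignettes/nalbuphine-poppk.Rmd` | methods and design notes |
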