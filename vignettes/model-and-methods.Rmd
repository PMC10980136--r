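---
title: "The model and methods behind antimiRsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The model and methods behind antimiRsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(antimiRsim)
```

antimiRsim simulates nanoparticle (NP)-delivered anti-miR-155 therapy in
non-small-cell lung cancer, alone or combined with cisplatin and the immune
checkpoint inhibitors (ICIs) atezolizumab and pembrolizumab. This vignette
explains the model, its assumptions, the default parameterization and how it
was calibrated, the numerical choices, and what the synthetic-data machinery
does and does not establish about real data.

## The ODE system

The model has two spatial compartments — plasma and tumor — and sixteen
states. All rates are per day; masses in mg; molecular species in pM; drug
concentrations in mg/mL; tumor volume in cm^3.

**Nanoparticle disposition.** Injected NP payload enters plasma as an
instantaneous mass increment and is lost to hepatobiliary clearance
(`k_Cl`) and metabolic degradation (`delta_NP`). Exchange with the tumor
interstitium is permeation-limited,

    J = P_NP * S * V * (NP_pl / V_pl - NP_int / (phi_int * V)),

with `S` the microvascular surface density (cm^2 per cm^3 tumor) and
`phi_int` the interstitial volume fraction. Vascular permeability carries a
Renkin-type size hindrance,

    P_NP = P_ref * (1 - Phi_NP / Phi_pore)^2,

so NPs larger than the vessel-wall pores do not extravasate, and smaller
NPs permeate better. Interstitial NPs reach cells by diffusion over the
intercapillary distance `Len`; the uptake rate constant is
`k_diff = D_NP / Len^2` with a Stokes-Einstein size dependence
(`D_NP ~ 1/Phi_NP`). Uptake splits between cancer cells and TAMs
(fractions 0.8/0.2) and payload release is lumped with internalization into
fixed effective cellular distribution volumes.

**The miR-155 axis.** Intracellular anti-miR-155 (`AM`) accelerates
miR-155 degradation through a saturable gain,

    dM/dt = g0 - delta_M * (1 + A_AM * AM / (EC50_AM + AM)) * M,

with `A_AM = 150`, so that saturating exposure multiplies turnover ~150x
and drives miR-155 from its 1.5 pM pre-treatment equilibrium to ~0.01 pM.
TAMs feed miR-155 to cancer cells through exosomes (`k_exo`); the
cancer-cell intrinsic production is offset so both cell types share the
1.5 pM drug-free equilibrium.

**Checkpoint biology.** PD-L1 is repressed by miR-155 through a Michaelis
term whose constant (`1.5/9` pM) pins a ten-fold PD-L1 rise under complete
miR-155 knockdown. PD-1 is a constant-turnover pool with a 1 pM
equilibrium. Free PD-L1 (mean over cancer cells and TAMs) and PD-1 form a
complex at equilibrium each instant; atezolizumab (anti-PD-L1) and
pembrolizumab (anti-PD-1) bind competitively, each inflating the effective
dissociation constant by `(1 + C/Kd)` — the antibodies are in vast molar
excess over the pM-scale receptor pool, so their free concentrations are
not depleted by binding. The complex `X` solves the quadratic
`X^2 - X(L + P + Kd_eff) + L*P = 0` (smaller root).

Immune kill is gated by a *saturable escape*:

    psi = 1 - E_esc * X / (K_I + X),   d_immun = delta_T * psi,

with `E_esc = 0.4` the maximal checkpoint-suppressible fraction of CD8+
T-cell killing. The bound reflects that part of the effector activity is
not PD-1:PD-L1 dependent. This form matters: with an unbounded hyperbolic
attenuation, complete miR-155 knockdown (PD-L1 up ten-fold) lets the tumor
escape immune kill almost entirely, which both caps the achievable clinical
benefit of high-dose anti-miR-155 and makes the low-dose response
non-monotone (the immune penalty of partial knockdown outruns the
proliferation benefit). Bounding the escape keeps the dose-response
monotone and preserves a clinically meaningful dynamic range, while the
factor still satisfies its structural limits: `psi = 1` when PD-L1 is
absent or the checkpoint is fully blocked by saturating antibody. A low
drug-free PD-L1 tone (0.15 pM against a 1 pM PD-1 pool and 1 pM complex
Kd) keeps the complex in its linear regime across the entire ten-fold
de-repression window, so the immune cost of knockdown accrues late rather
than early in the dose range — the second ingredient of monotonicity.

**Tumor growth.**

    dV/dt = gamma * Phi(M_c) * V * (1 - V/K) - d_chemo * V - delta_T * psi * V,

with `Phi(M) = 1 + (A_ML - 1) * M / (k_M + M)` the miR-155 proliferation
stimulus and

    d_chemo = delta_C * C / (IC50 * (1 + R_C * M/(k_M + M)) + C)

a saturable cisplatin kill whose IC50 is inflated ~6.5-fold at the miR-155
baseline (`R_C = 6.45`): the chemoresistance abstraction. Knocking down
miR-155 therefore both slows proliferation and re-sensitizes the tumor to
cisplatin — the mechanistic root of the anti-miR-155 + cisplatin synergy —
while simultaneously raising PD-L1 and dampening immune kill, the root of
the antagonism at unbalanced dose ratios. Immune and TAM cell densities are
treated as fixed effective fractions; explicit recruitment dynamics are an
extension point, not modeled.

Cisplatin and the ICIs follow one-compartment plasma kinetics with the same
permeation-limited tumor exchange as NPs, with drug-specific permeabilities
and clearances.

## Default parameterization and its anchors

Printed physiology is taken at face value: 0.02 kg / 1.5 mL plasma (mouse),
70 kg / 3 L plasma / 1.9 m^2 BSA (human), miR-155 equilibrium 1.5 pM, PD-1
equilibrium 1 pM, ten-fold PD-L1 de-repression. The remaining free mouse
parameters were calibrated by one-dimensional root solves (the calibration
module's machinery) against the preclinical reference design — inoculation
of a 0.1 cm^3 xenograft, treatment days 7–35, anti-miR-155 0.2 mg/kg twice
weekly, cisplatin 8 mg/kg weekly, atezolizumab 10 mg/kg and pembrolizumab
5 mg/kg twice weekly — to the end-of-treatment tumor-growth-inhibition
anchors: ~62% (anti-miR-155), ~49% (cisplatin), ~86% (combination), ~16%
(atezolizumab) and ~18% (pembrolizumab), with the control reaching
1.4 cm^3 at day 35. The solved knobs are the intrinsic growth rate, the
miR-155 proliferation gain, the NP permeability reference (median
per-injection tumor delivery ~2.5% of injected dose), the cisplatin kill
ceiling, the resistance gain, the immune kill ceiling and the two effective
antibody potencies. One anchor is structurally out of exact reach: with
anti-miR-155 and cisplatin each reproducing their monotherapy anchors, the
model's combination arm cannot fall below ~89% TGI (the effects compound);
89% is within a five-point band of the 86% anchor and we ship it rather
than distorting the resistance mechanism to force the midpoint.

The tuned constants are ordinary package defaults
(`default_mouse_parameters()`), and the pooled nonlinear least-squares
fitter (`fit_parameters()`) recovers them from synthetic multi-arm data —
the property the calibration tests exercise.

## Mouse to human

`scale_parameter_set()` applies the body-weight power law
`P_h = P_m * (BW_h/BW_m)^A` with per-class exponents: -0.25 for rate
constants, 0.75 for clearances, 1 for distribution volumes, -0.33 for
doses. Dimensionless gains, saturation constants, binding affinities and
tumor microarchitecture (vascular surface density, intercapillary
distance, NP and pore diameters) are size-invariant. The
human-equivalent-dose helper uses -0.25 by default because that exponent
maps the 0.2 mg/kg mouse dose to the 0.026 mg/kg human dose used
throughout the clinical simulations; -0.33, the classical dose-scaling
exponent, is available as an argument. The discrepancy between the two
conventions is real and we do not resolve it — we expose it.

Several human parameters are population-average overrides rather than
scaled values: physiology (weight, plasma volume, BSA), the initial
condition (a single founding cell, 1e-9 cm^3), the carrying capacity
(60 cm^3), the intracellular anti-miR-155 turnover (0.25/day, consistent
with near-complete washout between three-weekly doses), and the growth,
immune-kill and chemo-kill rates. The last three deserve emphasis: naive
allometric scaling of drug-effect rates under-predicts human treatment
effects, so they are re-calibrated against clinical behavior — an
untreated tumor reaching 1.5 cm diameter 124 weeks after inception (the
average patient's stage IA2 presentation), a control-arm median PFS of
~1.4 months, cisplatin monotherapy progressing at ~2.8 months, and
anti-miR-155 at its 2.5 mg/kg tolerability cap (Q3W) progressing at
~6.5 months. Re-anchoring drug-specific parameters to clinical
observations after interspecies scaling is standard translational
practice, and the carrying capacity matters here: it sets how strongly the
control arm is braked after presentation and was chosen so the virtual
cohort's control median PFS lands near 1.4 months.

## Response evaluation

Tumor growth inhibition compares a treated arm with its paired control at
an assessment day:
`TGI = 100 * [(V_ctrl - V0) - (V_trt - V0)] / (V_ctrl - V0)`, defined only
when the control has grown. RECIST 1.1 operates on the spherical diameter
`d = (6V/pi)^(1/3)` with a nadir-based reference: progressive disease
requires both a >= 20% and a >= 0.5 cm increase over the smallest diameter
recorded since treatment start; partial response is a 30% decrease from
baseline; complete response uses a 1 mm detectability floor (a guard — the
model never simulates CR). Assessments default to the daily simulation
grid (continuous in-silico monitoring); a trial-realistic cadence can be
passed explicitly. Months are days/30.44, fixed. New-lesion and non-target
RECIST rules are out of scope (single-lesion model).

## Sensitivity analysis

Sensitivities are measured for a *presenting* patient: a 1.5 cm baseline
lesion treated with 0.026 mg/kg Q3W for nine cycles, TGI at end of
treatment. Anchoring at presentation rather than re-growing the tumor from
inception under every perturbed parameter set keeps the response defined
across wide growth-rate perturbations (a fast-growing perturbed tumor
would otherwise saturate at carrying capacity before treatment even
starts; a slow one would never present). Points where the perturbed
control does not grow over the treatment window are flagged as undefined
rather than reported as near-singular ratios.

The global analysis perturbs 28 biological, transport and drug-effect
parameters simultaneously (Latin hypercube, multipliers uniform within
+-50%), regresses the standardized response on the standardized
multipliers, and reports the coefficients as sensitivity indices.
Replicate LHS designs give an SI distribution per parameter; one-way ANOVA
on |SI| with Tukey HSD groups the parameters into homogeneous letter
categories (a greedy compact-letter assignment: parameters are placed in
decreasing |SI| order into the first group with which no member differs
significantly). Defaults are 500 samples x 20 replicates, seed 155.

## Dose-response and prediction intervals

Dose grids default to 20 log-uniform doses between 1e-3 and 10 mg/kg under
QW, Q2W or Q3W schedules (25, 13, 9 cycles — a ~six-month course), with a
shared control arm. Two Hill forms are fitted by plain (unweighted) least
squares: `E = Emax / (1 + (EC50/D)^n)` for TGI, and
`E = Emin + (Emax - Emin) / (1 + (EC50/D)^n)` for the RECIST
diameter-change endpoint, where the zero-dose effect `Emin` exceeds the
high-dose plateau. Start values come from a logit-log linearization;
`n` is bounded to (0.05, 10] and `EC50` to within 10x the dose span.
`EC_p` inversion is closed-form: `D = EC50 * (p/(100-p))^(1/n)`.
Prediction intervals draw joint parameter sets (LHS, +-10% around baseline
for the ten sensitivity-ranked parameters), recompute the dose-response
per set and report empirical 5th-95th percentile bands; fewer than 100
sets is refused as unstable.

## Virtual cohorts

Virtual patients are lognormal multiplicative perturbations of the ten
sensitivity-ranked parameters, with sigma chosen so ~95% of proposals fall
within +-30% of baseline. Each proposal is grown untreated from a single
cell to week 124 and accepted iff the baseline diameter lies in the
stage IA window of 1-2.68 cm; generation is accept-reject and fully
seed-deterministic, with proposal counts retained for audit. The window is
defined on the diameter exactly (the equivalent volume window, 0.52-10.08
cm^3, is the rounded "0.5-10" of common usage). Because the window
conditions on 124 weeks of growth, acceptance concentrates the growth-rate
multiplier in a narrow band and lets the other parameters vary freely —
accepted patients are diverse in mechanism but constrained in
presentation, which is precisely what staging a cohort does. Treatment
simulations then restart at presentation: each patient's accepted baseline
volume, molecular species at that patient's own drug-free equilibrium.

## Synergy screening

Monotherapy dose grids per drug (log-spaced from 0.01 mg/kg to the
clinical cap: 2.04 mg/kg cisplatin = 75 mg/m^2, 17.14 mg/kg atezolizumab =
1200 mg, 2.86 mg/kg pembrolizumab = 200 mg, 2.5 mg/kg anti-miR-155) give
median-effect fits (regression of `log(fa/fu)` on `log D`), with fractions
affected `fa = TGI/100` clipped to [0.001, 0.999] and clipping counted.
Combinations are screened by Latin hypercube over non-constant dose
ratios (50 samples per combination by default) under the Q3W regimen with
cisplatin truncated at six cycles; each sample yields a combination index
`CI = sum_j D_j / D_x,j(fa)` and, when a cohort is supplied, a
Kaplan-Meier median PFS. Classification: CI < 0.3 strong synergy, < 0.9
synergy, <= 1.1 additive, > 1.1 antagonism. The threshold-rule miner
(`synergy_conditions()`) searches conjunctions of simple dose, dose-fraction
and total-dose predicates that maximize precision for a class; it is
descriptive bookkeeping over the screening table, not inference.

## Survival analysis

Kaplan-Meier estimation and Cox hazard ratios are delegated to the
survival package behind thin wrappers that fix the conventions: PFS from
RECIST-defined time to progression, censoring at the end of follow-up
(36 months in the full design; shorter horizons are used where the arms
progress early), median PFS as the first time the curve reaches 0.5.
Complete or near-complete separation of a high-dose arm from control makes
the Cox estimate run away; the wrapper flags these fits as degenerate
instead of reporting a vanishing point estimate, a deliberate choice of
statistical honesty over mimicking a printed number.

## Numerical choices

* Integration: `deSolve::lsoda` on a compiled C right-hand side (an exact
  transcription of the exported R evaluator, which the tests cross-check);
  doses are instantaneous plasma-mass increments with integrator restarts
  at each event; simultaneous events on one drug sum.
* Default tolerances 1e-8/1e-10 for reported simulations, 1e-6/1e-9 inside
  optimization/screening loops; a tolerance-halving test guards endpoint
  convergence.
* States are clipped to zero below integrator noise; an excursion below
  -1e-6 is an error, not a warning. The volume entering transport
  denominators is floored at one cell (1e-9 cm^3) so that
  extinction-strength treatments do not divide by zero.
* The miR-155 exosome rate must stay below the miR-155 turnover rate
  (validated), otherwise the shared 1.5 pM equilibrium would require a
  negative intrinsic production in cancer cells.
* Optimizer: bounded Levenberg-Marquardt (`minpack.lm`), residuals on
  natural-scale volume normalized per arm by the arm mean (log-scale
  residuals available); multi-start is log-uniform within bounds under a
  fixed seed with the best deviance kept.

## What the tests do and do not show

All packaged data are synthetic: the preclinical fixtures are the model's
own arm means under twice-weekly caliper-like sampling with lognormal
replicate noise, and the cohorts are parameter perturbations of one
average patient. Recovery tests (calibration, Hill, median-effect)
therefore demonstrate *internal consistency* — the estimators recover what
the generator put in, at the stated noise levels — not fidelity to any
real animal or patient. Test problem sizes are scaled to what the
estimators need rather than to the full defaults: calibration recovery
uses 20 seeded 5%-noise datasets with three free parameters; the virtual
trial uses 200 patients over a three-dose Q3W ladder plus control; GSA
property tests use reduced designs with a synthetic linear response as the
oracle. The full-size defaults (1,000-patient cohorts, 500x20 GSA, 50-way
screens) run through the same code paths via `run_experiment()`.

## Known limitations

No spatial heterogeneity (well-mixed compartments, uniform NP
distribution); no explicit T-cell/TAM population dynamics (fixed effective
densities); the TP53 network is abstracted into a single IC50 inflation;
no toxicity, dropout or inter-occasion variability; single-lesion RECIST
only. The combination-arm calibration floor discussed above is a
structural property of multiplicative effect compounding in this model
family. Allometric extrapolation plus clinical re-anchoring is a bridge,
not a validation: conclusions about human dosing inherit the model's
mechanism assumptions.
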