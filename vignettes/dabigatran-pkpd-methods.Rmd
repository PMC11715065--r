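---
title: "Methods: dabigatran PKPD modelling and bypass dose design in sheep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dabigatran PKPD modelling and bypass dose design in sheep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its models, defaults and
numerical choices. Units are fixed package-wide: minutes, litres,
milligrams, mg/L and kilograms; the allometric reference weight is 70 kg.

## Structural model

Dabigatran disposition is a two-compartment mammillary system with
zero-order inputs into the central compartment. Every administration is a
constant-rate infusion; a "bolus" is a short infusion at its actual
administration duration (1 min for dabigatran, 0.5 min for idarucizumab),
which matches how the doses were physically given and avoids the
discontinuity of an instantaneous input.

Parameters are clearances and volumes (CL, Q, V1, V2) standardised to
70 kg with exponents 0.75 (clearances) and 1 (volumes). The effect site is
a first-order lag of the plasma concentration,
`dCe/dt = keo (C1 − Ce)`; the rate constant is stored on its reported
scale as the half-time `T½keo = ln 2 / keo`, because that is the scale on
which its magnitude is interpretable (how quickly R-time tracks plasma
concentration). Neither the half-time nor any response parameter is
weight-scaled: there is no theoretical basis for scaling an equilibration
delay or a potency with size, and the study estimated them as
size-independent.

Reaction time follows the sigmoid Emax model
`R = E0 + Emax·Ce^N/(Ce50^N + Ce^N)`. The idarucizumab reversal effect is
deliberately empirical: a unit amount enters a reversal-effect compartment
over `DUR_IDA` minutes and leaves at rate `K_IDA`; R-time decreases by
`SLOPE_IDA` per unit of compartment amount. Because the input is
unit-normalised (one "unit" per dose regardless of milligrams), no dose
proportionality across idarucizumab dose levels is assumed — a single dose
level was studied, so the data cannot inform one. Observed R-time is the
sum of the dabigatran and reversal effects, floored at zero: reaction
times are physically non-negative, and with a large reversal slope the
additive model could otherwise go negative.

## Two evaluation paths

The default path is closed-form: all inputs are zero-order, so C1, C2 and
(by exact first-order convolution) Ce are finite sums of truncated
exponentials; an infusion over `[t0, t1]` is the superposition of one
switched on forever at `t0` minus one switched on at `t1`. This is exact
up to floating point and fast enough for the inner loops of the
mixed-effects objective. The second path integrates the same equations
with `deSolve::lsoda` piecewise between dose-event edges (so the input
rate is constant within each integration segment) at `rtol = atol =
1e-10`. The two paths are compared in the test suite to a relative
tolerance of 0.1% and mass balance (administered = in body + eliminated)
is checked analytically on the closed form.

Two degenerate configurations are guarded numerically: repeated
disposition eigenvalues (impossible for distinct positive rate constants
except on a measure-zero set) and `keo` resonant with a disposition
eigenvalue; both are handled by a relative nudge of `1e-7`–`1e-9`, which
perturbs trajectories far below the 0.1% equivalence tolerance.

## The synthetic cohort generator

`generate_cohort()` reproduces the study layout: n sheep, dabigatran
4 mg/kg IV over 1 min at time 0, idarucizumab 15 mg/kg over 0.5 min at
120 min, both channels sampled at 5, 15, 30, 60, 90, 120 min and then 5,
15, 30, 60, 120, 240, 480 min and 24 h after idarucizumab (the
per-protocol schedule; a condensed summary list that differs slightly is
not used). Weights are
drawn uniformly from 50–80 kg — the study's demographic table is not
reproduced here, so this range is a documented stand-in, configurable in
`study_design()`.

Between-subject variability is log-normal with a diagonal covariance (no
BSV correlations were reported): each parameter is
`typical × (W/70)^EXP × e^η`. Residual error is
`y = f(1 + ε_prop) + ε_add` with independent normal components per
channel; the study names both components but not their combination rule,
and this independent-additive combination is the common convention.
Observations that sample negative are truncated at zero and flagged
(`TRUNC = 1`) rather than resampled — resampling would silently distort
the error model the estimator assumes.

Defaults for quantities without reported values, chosen once as plausible
for this system and not revisited:

* `E0 = 6` min — midpoint of the normal 4–8 min R-time range.
* `N = 1` — no evidence on curve steepness; the simplest member.
* BSV 30% CV (ω² = 0.09) on CL, Q, V1, V2 and E0. PD variability beyond
  the baseline is left at zero: with cohorts of study size, additional PD
  variances are weakly identifiable and would mostly add noise to the
  recovery experiments.
* Residual error: concentrations 10% proportional + 0.1 mg/L additive;
  R-time 10% + 0.5 min.
* Reversal effect: `K_IDA = ln 2 / 10` (10-min washout half-life),
  `DUR_IDA = 0.5` min, `SLOPE_IDA = 6.9` — tuned so a 15 mg/kg dose at
  120 min lowers R-time by ≈5 min at the first sample 5 min later, the
  reported magnitude; these three are explicitly *not* reported estimates.

What the generator does **not** emulate: assay quantification limits,
inter-occasion variability, covariates other than weight, and any
mechanism-based binding between idarucizumab and dabigatran (the reversal
model is additive-empirical). Passing tests therefore demonstrate internal
consistency of model, simulator and estimator — not that real sheep data
would estimate this cleanly.

## Estimation

The marginal likelihood is approximated per subject. The inner problem
finds the conditional mode η* of
`m(η) = Σ[log 2πv + (y − f)²/v] + η'Ω⁻¹η` with
`v = (f σ_prop)² + σ_add²` (the proportional component is evaluated at the
*individual* prediction — the "interaction"). The subject's contribution is
`m(η*) + log|Ω| + log|M|`, where for Laplace `M` is half the numeric
Hessian of `m` at the mode, and for FOCE-I the Gauss–Newton form
`Ω⁻¹ + Σ_j w_j g_j g_j'` with `g_j = ∂f_j/∂η` and
`w_j = 1/v_j + 2(f_j σ_prop²)²/v_j²` (the second term carries the
variance sensitivity). Naive pooling sets η ≡ 0 and drops the Ω terms —
and with it any ω estimation, whose gradient would be identically zero.

All estimated quantities (fixed effects, variances, residual components)
are searched on the log scale, which enforces positivity and makes the
quasi-Newton scaling natural. The outer optimiser is an optional short
Nelder–Mead stage followed by `nlminb` (PORT), with box bounds ±15 on the
log scale to stop runaway excursions. The default relative tolerance
(1e-5, or 1e-4 in the heavier experiments) corresponds to the
three-significant-digit convergence criterion conventional in
pharmacometric estimation. Initial values come from non-compartmental
heuristics
(`initial_estimates()`: V1 from dose/Cmax, CL from dose/AUC, baseline and
span of observed R-times), user-overridable. PORT's "false convergence"
on this numerically approximated objective is classified as
converged-with-note (`convergence$clean = FALSE`): it almost always means
the finite-difference gradient noise floor was reached, not a wrong
optimum.

The sequential PPPD scheme fits the concentration channel first; stage 2
fixes the population PK fixed effects, variances and concentration
residual components at the stage-1 estimates, keeps the concentration data
in the likelihood so each subject's PK random effects remain informed, and
estimates the response parameters (E0, Emax, Ce50, T½keo, SLOPE_IDA by
default; the reversal input duration and elimination rate stay fixed at
their configured values, since a handful of post-reversal samples cannot
separate all three reversal parameters). Standard errors, when requested,
come from a numeric Hessian of the objective at the optimum with
`CI = estimate × exp(±1.96·SE_log)`.

Model comparison uses the objective reduction against χ²: 3.84 at one
degree of freedom for α = 0.05. The test suite calibrates this decision on
400 null replicates (full model re-estimating the Hill coefficient that
the generating model holds at 1) and checks the empirical rejection rate
against its binomial interval around 5%.

## Visual predictive checks

`run_vpc()` simulates replicate cohorts from the fitted (or supplied)
population at the observed design. Observations and simulations are
prediction-corrected (`y × pred_bin/pred_record`, with the bin reference
being the median typical-subject prediction) and summarised as 10/50/90th
percentiles per nominal-time bin; 95% confidence bands for each percentile
come from the replicate distribution. Binning is by nominal sampling time
because the design is nominal-time sampled; bins with fewer than three
observations are merged into a neighbour and the result flagged.
Percentiles use linear interpolation (R's default type 7) — stated because
percentile conventions differ across VPC implementations. The default
replicate count is 500–1000; the self-consistency experiment in the test
suite uses 500, at which the band Monte-Carlo error is well below the band
width.

## Bypass dose design

During bypass the circuit is a third exchanging compartment: prime volume
V3, pump flow Q3, no elimination. The system is integrated in amounts
(`a1' = rate_in + Q(C2−C1) − CL·C1 + Q3(C3−C1)`, `a2' = Q(C1−C2)`,
`a3' = Q3(C1−C3)`), which conserves mass by construction; the symmetric
exchange form `Q3(C1−C3)` is the only formulation consistent with a pump
that moves the same flow in both directions and adds no elimination.
Circuit defaults V3 = 1.0 L and Q3 = 2.0 L/min are sheep-scale
configurable stand-ins; the exact values behind the published simulation
are not reproduced in the available material, which is why the
time-averaged concentration check carries a ±20% band.

The circuit is attached at time 0 already primed to the target
concentration; the prime dose is `target × V3`. `design_regimen()` uses a
loading dose of `target × V1` (per kg) and finds two stepped maintenance
rates by Nelder–Mead on log rates, minimising the mean squared relative
deviation of simulated plasma concentration from the target over the
maintenance window (default from 10 min to the horizon). The search is
deterministic; the returned plan carries its own achieved maximum
deviation, and re-simulation reproduces that report exactly. The target
R-time is an input (`concentration_to_target_effect()` inverts the Emax
model), because the source material quotes both 13 and 16 min as suitable
targets — the package does not adjudicate.

## Problem sizes and known limitations

The recovery experiments use 20 subjects with the study schedule plus
early samples at 1, 2 and 3 min: with a 1.04-min equilibration half-time
and a first routine sample at 5 min, the effect site is already at ≈96% of
plasma by the first observation, so T½keo is not identifiable from the
routine schedule alone — dense early sampling is what "rich" means here.
The acceptance script averages estimates over five independent cohorts;
the test suite uses a single cohort. Five-subject cohorts at the study's
sparse schedule give visibly noisier PD estimates (see the README
example); that is a property of the design, not of the estimator.

Known limitations: no covariate models beyond allometric weight scaling
(renal function drives dabigatran clearance in vivo but was not modelled);
the reversal model is empirical and single-dose; no inter-occasion
variability; FOCE-I/Laplace are asymptotic approximations and their small-
sample behaviour at n = 5 is exactly as rough as the README example shows;
hemodilution and temperature effects on parameters during bypass are out
of scope.
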