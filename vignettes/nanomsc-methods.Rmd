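---
title: "Mechanism-based PK-PD modeling of nano-engineered MSC drug delivery: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanism-based PK-PD modeling of nano-engineered MSC drug delivery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The system being modeled

Nano-engineered mesenchymal stem cells (nano-MSCs) are MSCs loaded with
paclitaxel (PTX)-bearing PLGA nanoparticles. After an IV dose in a
tumor-bearing mouse, the drug exists simultaneously in three physical
forms — free PTX, nanoparticle-bound PTX, and MSC-associated PTX — each
with its own disposition. `nanomsc` implements a three-layer
compartmental model of this system in the orthotopic A549 lung-tumor
mouse, the estimation workflow used to parameterize it, and the
simulation studies built on it.

### The PK layers

Each small-molecule layer (free drug; NP-bound drug) is a
three-compartment model — central, peripheral, tumor — with linear
elimination (`CL`) from the central compartment, distributional clearance
(`CLD`) to the peripheral compartment, and tumor uptake by two parallel
processes of Krogh-cylinder type:

* vascular exchange, permeation across the capillary endothelium, with
  rate coefficient `2 P Rcap / RKrogh^2` (per unit tumor volume), and
* surface exchange, diffusion across the tumor surface, with coefficient
  `6 D / Rtumor^2`,

both acting on the gradient `Cc * E - Ct`, where `E` is the tumor
accessible fraction. The MSC carrier layer has no systemic clearance;
its central compartment empties through two unidirectional extravasation
processes (`Kct` to tumor, `Kcp` to peripheral). The layers are chained
by first-order mass transfer: exocytosis moves drug from every MSC
compartment into the matching NP compartment at `Kexo` (PTX-mass basis),
and release moves drug from both the NP and MSC compartments into the
matching free-drug compartment at `Krel` (the intracellular free drug is
assumed to efflux instantaneously, so release is rate-limiting in both
layers).

Amounts are in ng PTX-equivalent, volumes in mL, time in h. The plasma
observation sums the central concentrations of the layers present in an
arm, with the free and NP concentrations multiplied by their
plasma-to-blood ratios `fu` (the MSC layer carries no such ratio); the
lung observation is the total tumor-compartment amount over the tumor
volume. These conventions are the only ones consistent with the
reported parameter sets; the direction of the `fu` scaling (multiply
rather than divide) is isolated in `observed_plasma_concentration()`.

### The PD model

Tumor burden `TV` (bioluminescence, 1e6 photon/s) grows exponentially at
an arm-specific `Kg0` and is reduced by three parallel kill terms driven
by the tumor-compartment concentrations: saturable (Emax-type) kill for
free and NP-bound drug (`Kmax C / (IC50 + C)`) and linear kill
(`K_MSC * C`) for MSC-associated drug. During PD integration the tumor
geometry is dynamic: `VT = a TV^b` through the power calibration and
`Rtumor` by the sphere relation, recomputed at every evaluation and fed
back into all exchange terms and concentrations. A power function keeps
`VT` positive at any burden. One log-normal random effect acts on the
baseline `TVBL`; residual error is proportional with arm-specific CVs.

## Parameters and defaults

`nanomsc_params()` carries the canonical parameter set of the modeled
study: literature exchange constants (`P`, `D`, `E` per layer, `Rcap`,
`RKrogh`), the in-vitro-derived `Krel = 0.0085`/h and `Kexo = 0.081`/h
(the mass-scaled in-vitro value 0.083 was relaxed to 0.081 by an OFV
profile in the original workflow; `profile_kexo()` exposes the same
device), the reported PK estimates for all three layers, and the
reported PD estimates including `omega_TVBL = 0.964` (log scale) and the
four arm CVs. The implied 0.02 kg body weight converts mg/kg doses; one
million MSCs carry 25 ug PTX-equivalent.

**The bioluminescence calibration.** The exponents of `VT = a TV^b`
were never reported. The package default (`a = 0.4`, `b = 0.25`) is
pinned by two consistency requirements: the tumor volume should be near
the 0.3 mL value assumed for the static-geometry PK analysis at
early-study burdens (`TV` below ~1), and should stay mouse-plausible
(~1 mL) at the endpoint burdens (`TV` ~ 60) where control animals die.
Steeper calibrations make the reported `K_MSC` eradicate the simulated
tumor under the reported regimen — shrinking volume concentrates the
drug, a runaway `C = A/VT` feedback — which contradicts the partial
inhibition the model is known to produce. Because the calibration is a
package choice, recovery studies use it for both generation and
fitting.

## Estimation workflow

**In-vitro fits.** `Krel` comes from a first-order association fit to
cumulative release (`plateau (1 - e^{-Krel t})`), `Kexo` from a
first-order decay fit to retained NP fraction, both by nonlinear least
squares with log-parameterized rate constants and log-linear starting
values — robust on 5-8 point datasets. The NP-mass `Kexo` is multiplied
by the 0.148 mg/mg drug loading because the PK model tracks PTX mass.
The calibration `(a, b)` is ordinary least squares on `log(VT)` vs
`log(TV)` (the spreadsheet power-trendline procedure), at 1 g/mL tissue
density.

**Naive-pooled PK, layer by layer.** The destructive-sampling design
(one sample per animal) supports no between-subject variability, so the
PK likelihood is exact pooled ML with proportional error — what a
first-order method degenerates to without random effects. The free-drug
layer is fitted to the PTX-solution arm; its estimates are then fixed
and the NP layer fitted to the NP arm; both are fixed under the MSC
layer fit. Plasma and lung carry separate error CVs in every fit (six
in total). Parameters are optimized on the log scale with jittered
multi-starts and a Nelder-Mead polish; RSEs come from the inverse
Hessian via the log-scale delta method; `sir_uncertainty()` adds
sampling-importance-resampling CIs (single pass, proposal covariance
inflated 1.5x).

With static geometry all three layer models are linear, so the fits run
on matrix-exponential trajectories (`solve_pk_linear()`) — exact, no
truncation error. Identifiability at the study design is limited in
known ways: `Kct` and `Kcp` enter the sampled times (2 h onward) only
through their ratio once the fast plasma phase (lumped rate ~11.7/h,
half-life ~0.06 h) has decayed, and `V_MSCcentral` is informed only by
plasma samples taken long after that phase; the Hessian-based RSEs flag
both. `V_MSCperipheral` appears in no differential equation and is
carried but never estimated.

**Population PD (Laplace + modified M3).** The PD fit is sequential
(PK fixed, IC50s fixed to their literature values) and joint across
arms: arm-specific `Kg0`, `TVBL`, and error CVs, the three kill
parameters, and `omega_TVBL`. The marginal likelihood over the scalar
random effect is approximated by the Laplace method: per animal, the
joint -2 log-density is minimized over `eta` by a safeguarded Newton
iteration and corrected by the log of its curvature. Dropout is handled
by the modified M3 device: each animal's maximum observed value becomes
its upper "detection" limit (the maximum itself stays a continuous
record), scheduled times missing after the last observation are
materialized as censored records, and each contributes its exceedance
probability `1 - Phi((ULIM - f)/(sigma f))`.

The 17-parameter surface is optimized in stages for conditioning — the
control-arm block first (closed-form trajectories), then each treated
arm's block against its own animals, a one-dimensional `omega` pass over
all animals, and a joint polish — so the reported estimate is the joint
optimum reached from a strong initialization. Two numerical choices
matter here: the inner Newton iterates to a start-independent tolerance
(1e-6), because the outer optimizer differences the OFV at ~1e-8
parameter steps and any warm-start hysteresis would corrupt those
gradients; and the eta finite-difference step is a deliberately coarse
0.02, because second differences at tiny steps amplify solver-tolerance
noise into the curvature term.

The Laplace approximation itself carries a small, uniform skew bias for
this model — about +0.016 OFV units per animal against 64-node adaptive
Gauss-Hermite quadrature, regardless of censoring — which stays inside
half an OFV unit at the 32-animal study scale; the test suite pins both
scales.

## Trajectory engines

Three routes solve the same equations, used where each is strongest and
cross-checked in the tests:

* `solve_pk_linear()`: matrix-exponential propagation of the
  static-geometry linear system (eigendecomposition with an `expm`
  fallback); exact; the PK-fit hot path.
* `solve_pkpd_ode()`: `deSolve::lsoda` with the compiled right-hand
  side; the reference numerics (default `rtol 1e-8`, `atol 1e-10` ng —
  the system is stiff: free-drug tumor exchange equilibrates at ~2000/h
  against release at 0.0085/h) and the simulation route.
* `solve_pkpd_etd()`: a block-analytic exponential integrator for the
  PD-estimation hot path. The stiffness lives in closed linear
  sub-blocks — the MSC cascade is solved in closed form, each
  central-tumor pair by an exact 2x2 matrix exponential with
  substep-averaged inflows, the rest by exact scalar exponential
  updates — so only slow rates enter the error term. Substeps refine to
  0.02 h for 6 h after each dose (the carrier-to-tumor build-up peaks
  ~0.4 h post-dose) and run at 0.5 h elsewhere; agreement with the
  lsoda route is ~3e-4 relative on the study trajectories at ~6x less
  cost per solve. The synthetic-data generators deliberately use the
  lsoda route at tight tolerance, so recovery studies never fit with
  the same numerics that generated the data.

Dosing is instantaneous boluses into the target layer's central
compartment; integration always starts at t = 0, doses at t <= 0 are
initial conditions, and an output falling exactly on a later dose time
reports the pre-dose state (the lsoda event convention). TV is floored
at 1e-6 inside the geometry calibration and at the prediction boundary,
guarding the power function and the proportional-error likelihood
against solver overshoot through zero burden.

## The synthetic studies

No data are shipped; `generate_*()` functions emulate the original
designs as pure functions of (truth, design, seed):

* **PK study:** 3 formulation arms x sacrifice times {2, 24, 48, 120,
  288} h x 3 mice, plasma and lung from each mouse, single 5 ug IV
  bolus, proportional error with the arm/tissue CVs of the reported
  parameter set (up to 116%). Each record is a distinct animal.
  Nonpositive simulated concentrations are excluded, as zero measured
  concentrations were in the original analysis; the estimator does not
  model that truncation, which contributes a small downward bias in
  recovered clearances at the noisiest tissue.
* **PD study:** four arms (pooled control; 40 mg/kg free drug or NP on
  days 0/4/8; 1e6 MSC loading plus 0.5e6 q14d maintenance), 8
  animals/arm (the real per-arm counts were not reported; configurable),
  twice-weekly sampling over 63 days (1512 h), log-normal baseline BSV,
  proportional error. Dropout: an animal dies at the first scheduled
  visit whose noisy measurement would exceed the threshold (default 60,
  about the typical control endpoint burden), and that measurement is
  never recorded. Death selecting against high *observed* values is
  what masks treatment effects in naive analyses and is the mechanism
  the modified-M3 likelihood repairs; a latent-threshold rule was
  evaluated first and discarded because, with BSV on baseline only, it
  produces no such selection and the M3-vs-drop comparison degenerates.
* **In-vitro and calibration sets:** release/retention time courses and
  weight-bioluminescence pairs (n = 8, log-uniform burdens) with
  proportional noise.

What these generators do not emulate: real bioluminescence noise is
heavier-tailed and partly systematic (imaging geometry, substrate
kinetics), real dropout also has drug-toxicity and handling components,
and the real release profile is matrix-controlled (a Higuchi-type law)
rather than exactly first order. Passing recovery tests therefore shows
the estimators are correct and well-behaved under the model's own
assumptions, not that the model is right for any particular dataset.

## Simulation studies

`scenario_grid()` reproduces the dosing and parameter scans: equal-total
-dose interval variations (maintenance 0.5e6 q14d / 0.25e6 q7d /
0.125e6 q3.5d, maintenance window through day 56 so the cumulative dose
matches exactly), maintenance-dose variations (0.25/0.5/0.75/2 x 1e6
q14d), and `Krel` {0.00425, 0.0085, 0.017} / `Kexo` {0.06, 0.081, 0.1}
variations at the original regimen. Population summaries (median and
10th/90th percentiles over n = 100 subjects) carry BSV only; residual
error is available behind a flag for predictive-check use. The horizon
is 1512 h. The qualitative findings — burden falls with dose, rises
with `Kexo`, and is comparatively flat across intervals and `Krel` —
are asserted in the test suite.

## Diagnostics

`pcvpc()` implements the prediction-corrected VPC: replicate studies
are simulated at the observed design with BSV, residual error, and the
dropout *rule* (not the observed dropout times, so censoring is
endogenous), and observed and simulated values are corrected by the
bin-median population prediction over the record's population
prediction. Bins are the nominal sampling times — the designs have
fixed schedules, and data-driven binning on sparse designs only adds
noise. `gof_table()` emits population predictions, individual
predictions at the empirical Bayes modes, and proportional residuals;
censored records carry no residual.

## Problem sizes used by the shipped analyses and tests

The analysis scripts run the full study designs once (100-subject
scenario grids, 200-replicate VPC). The test suite sizes its Monte
Carlo studies to stay informative at reasonable cost: 100 replicate PK
recovery fits, 5 replicate four-arm PD recovery fits, 25 paired
M3-vs-drop control fits, 60-100 replicate in-vitro recovery studies.
These counts are the package's own choices; the underlying study
designs are never scaled.

## Known limitations

* `Kct`/`Kcp` and `V_MSCcentral` are structurally near-unidentifiable
  at the sampled times (see above); their point estimates should be
  read together with their RSEs.
* The Laplace skew bias (~0.016 OFV units/animal) is intrinsic; an
  exact-quadrature marginal is available in the test helpers but is not
  an estimation mode.
* The release model is first order by design; matrix-release kinetics
  are out of scope.
* SIR runs a single proposal/resampling pass; heavily non-elliptical
  surfaces would need iterated proposals.
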