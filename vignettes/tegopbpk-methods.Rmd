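---
title: "Model and methods: coupled PBPK/PD simulation of tegoprazan and M1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: coupled PBPK/PD simulation of tegoprazan and M1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tegopbpk)
```

## Scope and structure

`tegopbpk` simulates the oral pharmacokinetics of tegoprazan — a weakly
basic (pKa 5.1), highly permeable, poorly soluble-at-neutral-pH
potassium-competitive acid blocker — together with its metabolite M1, and
couples the predicted plasma concentration to an indirect-response model of
intragastric pH. Because tegoprazan raises the pH of the very compartment
it must dissolve in, the pharmacology feeds back on the absorption: the
model integrates absorption, disposition and response as one ODE system
rather than chaining them.

The pipeline has four stages, each usable on its own:

1. *In-vitro calculators* turn assay tables (substrate depletion, Caco-2
   transport) into clearance and permeability parameters.
2. *Physiology and absorption* build a virtual subject (organ volumes,
   flows, hepatic scaling factors, nine-segment GI tract) and the
   dissolution/transit/uptake model.
3. *Disposition and PD* assemble the whole-body model for the parent, the
   minimal model for M1, and the gastric-pH turnover model.
4. *Verification* summarizes simulated populations by non-compartmental
   analysis and predicted/observed ratios with a 0.7–1.3 acceptance window.

## In-vitro parameter derivation

Substrate-depletion assays are fitted by ordinary least squares on
log-percent-remaining against time over all points with positive remaining
fraction; for a mono-exponential the terminal slope equals the full-series
slope, and the package samples only five timepoints, so no lag-phase
handling is applied by default. Microsomal intrinsic clearance is
`CLint = k / C_protein` with the protein concentration in mg/µL, which
yields µL/min/mg directly; this convention reproduces the two shipped
model inputs (15.96 µL/min/mg for the parent, 2.353 for M1) from their
generating rate constants, closing the unit loop. Recombinant-CYP
clearance uses the half-life form with the assay's fixed 1400 µL
incubation volume and the total CYP amount as an explicit argument, since
stock concentration alone does not determine the amount in the tube.

Caco-2 permeability is the per-replicate OLS slope of cumulative
transported amount against time divided by donor concentration × filter
area (default 1.12 cm², the standard 12-well insert); replicates are
averaged arithmetically and reported with SD, and the efflux ratio is the
B→A/A→B quotient of mean permeabilities. Efflux below 2 justifies the
absence of a transporter term in the absorption model.

## Virtual subjects

The reference subject (70 kg) carries standard published organ volumes and
regional blood flows, MPPGL 40 mg/g, CPPGL 80.7 mg/g, HPGL 120 × 10⁶/g,
and typical hepatic CYP abundances (3A4 137, 2C19 14, 2C8 24, 2C9 73,
2D6 8, 2E1 61 pmol/mg). These are deliberately explicit, editable numbers:
the original model was built on a proprietary simulator population whose
values are not published. Inter-individual variability is independent
log-normal (mean-preserving) on body weight, volumes, flows, MPPGL and CYP
abundances, with default CVs of 15/15/15/30/40% — an assumption surface,
not data; the generator documents it and the tests check that the sample
CV and mean converge to the configuration. Volumes scale allometrically
with body weight (exponent 1), flows with exponent 0.75. Demographics
follow the virtual-trial design: ages uniform on 20–40, male:female 1:1.

## Gastrointestinal absorption

Nine segments in series (stomach, duodenum, jejunum I–II, ileum I–IV,
colon), each holding solid and dissolved drug. Transit is first-order with
standard human mean residence times (gastric 0.4 h fasted; small intestine
≈3.6 h total; colon 13.5 h). Dissolution follows the Nernst–Brunner
diffusion-layer form for monodisperse shrinking spheres with
`h = min(r, 30 µm)`; the particle radius is floored at 1% of its initial
value so the cube-root law stays Lipschitz as the solid vanishes — without
the floor the ODE right-hand side has unbounded curvature at zero solid
mass and adaptive solvers stall. Solubility is log-linearly interpolated
through the three anchored points (223, 0.7, 0.02 mg/mL at pH 1, 3, 6.8);
a Henderson–Hasselbalch mode exists but is not the default because the
anchored points are inconsistent with HH at pKa 5.1. Dissolved
concentration above local solubility precipitates first-order (default
4/h); above the supersaturation cap (default ratio 10) a fast clamp
(500/h) enforces the ceiling, so transit of dissolved drug into a
low-solubility segment cannot build unbounded supersaturation.
Formulation defaults (30 µm radius, density 1.2 g/mL, D = 9×10⁻⁶ cm²/s)
are declared assumptions exposed in the configuration; the source model
used unpublished simulator defaults.

Absorption from each intestinal segment is `ka = 2·Peff·SEF/r` applied to
dissolved amount, with a surface-enhancement factor of 10 for the small
intestine (plicae and villi accessible to a high-permeability compound), 1
for the colon, 0 for the stomach. The effective permeability is the
model-final optimized value 1.0×10⁻⁴ cm/s by default, with a log-linear
Caco-2 calibration available. M1 is formed in the liver and has no
absorption stage. Mass leaving the colon counts as unabsorbed; the mass
balance dose = lumen + absorbed + body + eliminated + exited is asserted
to 0.1% (and holds to machine precision).

## Disposition

The parent uses a full perfusion-limited PBPK model (11 tissues, venous
and arterial blood, lung in series). Tissue partitioning follows the
Rodgers–Rowland tissue-composition method in its very-weak-base branch
(ionization at plasma pH 7.4 / intracellular pH 7.0, neutral lipid and
phospholipid partitioning, extracellular albumin binding), multiplied by a
global Kp scalar. The scalar is calibrated by bisection so the computed
Vss (ΣKp·V/BW plus plasma) equals 1.0 L/kg, the model-final target; Vss is
linear in the scalar, so bisection converges tightly and the calibration
round-trips. Hepatic elimination is well-stirred: unbound intrinsic
clearance (IVIVE: Σ per-pmol CYP clearances × abundance + additional HLM
clearance, × MPPGL × liver mass; biliary clearance per 10⁶ hepatocytes ×
HPGL) acting on unbound liver-exit blood. Renal clearance acts on arterial
plasma in the kidney, the additional systemic clearance on venous blood —
the original table does not state its site, so the venous choice is
documented here. Biliary drug counts as eliminated (no enterohepatic
recirculation).

Standard IVIVE of the shipped rCYP intrinsic-clearance values produces a
hepatic clearance substantially higher than the clearance the original
simulator reported with the same inputs; the proprietary scaling between
those numbers is unpublished, so this package implements the standard
scale-up and treats absolute exposure as model output, not as a
reproduction target. Consequently the package's verification stage runs
against its *own* synthetic observed data, and the shipped published
summary tables are used only for the arithmetic checks (ratios, percent
changes) that do not depend on re-simulation.

M1 uses a minimal PBPK model: one central compartment (Vss 1.72 L/kg,
plasma-referenced) exchanging with a single adjusting compartment
(k_in 40/h, k_out 7.76/h, V_sac 1.23 L/kg), fed by the parent's hepatic
metabolic flux (fraction `fm_metabolite`, default 1, with the additional
clearance terms absorbing any mismatch — the source model was likewise
fitted, not mechanistic). Elimination is whole-organ metabolic clearance
(HLM scaled by MPPGL + HLC scaled by CPPGL through the well-stirred liver)
plus renal and additional clearances.

## Gastric-pH pharmacodynamics

The drug-free baseline is a sixth-order Fourier series with a 24-h period.
The shipped default is the constant 1.49 — the default baseline used when
the response is disabled — because the fitted circadian coefficients were
never published; `fit_fourier_baseline()` recovers a full coefficient set
from any 24-h recording by linear least squares (an exact projection,
idempotent on its own output).

The response model is indirect: a sigmoid-Emax effect of plasma tegoprazan
multiplies the baseline and drives a turnover equation. As printed, the
turnover adds the baseline a second time (the effect term already contains
it), which would double the drug-free steady state; the default "reduced"
mode therefore drops the extra term and ties k_in = k_out so the drug-free
response equals the baseline exactly, while an "as_printed" mode preserves
the literal equation — both are tested, and the reduced mode's drug-free
fixed point and the printed mode's doubled steady state are each asserted.
The statement that k_in "is" the plasma concentration is treated as a typo
for the turnover input rate constant.

The gastric pH used by dissolution is `clamp(R, 1, 8)`; in the fed state a
meal-buffer elevation (initial pH 4.5 decaying at 0.693/h to the fasted
baseline) is added. Feedback is per subject — each virtual subject's own
plasma profile drives their own gastric pH. The holding rate (percent of a
24-h window with pH ≥ 4, threshold inclusive) is computed per subject with
linear interpolation of threshold crossings and then averaged; computing
it on the mean pH profile instead is available by summarizing the mean
trajectory, but per-subject averaging is the default since the endpoint is
defined per patient.

**Nominal PD parameters.** No fitted values of Emax, EC50, γ, k_in, k_out
were published. The shipped nominal set (Emax 6, EC50 10 ng/mL, γ 1.2,
k_in = k_out = 0.2/h) was chosen once so that a single 50 mg dose in the
reference subject holds pH ≥ 4 for about half of the first 24 h — the
magnitude reported for that regimen — and then frozen. The small k_out
encodes the long-lasting acid suppression of this drug class relative to
its plasma half-life; the low EC50 compensates for this model's lower
absolute plasma exposure (see Disposition above). Parameter *recovery*,
not the nominal values, is the tested surface: fitting synthetic pH data
generated at known parameters returns them to <1% noise-free, with
bounded EC50 bias under 5% proportional noise.

Fitting uses Levenberg–Marquardt on log-transformed parameters. The
prediction inside the fitter exploits the linearity of the turnover
equation in R: the effect trajectory is interpolated piecewise-linearly on
a fine grid and convolved exactly with the exponential kernel (a linear
recurrence), which is fast, smooth in the parameters — finite-difference
Jacobians over an adaptive ODE solver are too noisy for reliable
convergence — and independent of the `lsoda` route used by the data
generator, giving the round-trip test two genuinely different numerical
paths.

## Simulation engine

One monolithic state vector (51 states: 9×3 luminal + colon exit, 13
parent compartments, 4 parent elimination integrals, M1 central + SAC + 3
integrals, pH response) integrated by `lsoda` at rtol 1e-8 / atol 1e-10 mg
with doses as solid-mass impulses into the stomach and a 48-h washout
after the last dose. Output resolution is 5 min (holding-rate accuracy);
concentrations are reported in ng/mL, amounts held in mg internally.
Stored states at an event time are pre-impulse, and the mass-balance
bookkeeping counts a dose only strictly before an output time. Elimination
integrals are carried as states so conservation can be asserted at every
output time; tolerance refinement by 10× changes AUC by <0.01%.

The virtual-trial design is 10 trials × 100 subjects with per-trial seeds
derived from a master seed. The test suite and the acceptance script run
reduced designs (2 × 12 subjects; the PD noise study at 40 seeds; the
population-convergence check at n = 5000 draws without simulation) — these
sizes are the package's choice to keep the default run fast while leaving
the full design available through the same arguments.

## Fed state

A high-fat meal multiplies the gastric mean residence time by 2.704 (the
+170.4% printed for the fed prediction), raises duodenal/jejunal bile salt
concentrations five-fold (inert unless a solubilization coefficient is
set; default off pending data), and elevates initial gastric pH to 4.5
with first-order return. Gastric emptying stays plain first-order with the
slower rate rather than adding a lagged clock: a dose-relative lag does
not compose with repeated dosing inside one autonomous ODE system, and the
residence-time calibration is what the single printed constraint pins
down. The fed simulation reproduces the qualitative food effect — lower
Cmax, delayed Tmax, near-unchanged AUC — which is the behavior the
verification stage asserts.

## Numerical choices and degenerate inputs

* Radius floor 1% of initial radius in the dissolution law (Lipschitz
  regularization; below the floor the rate is linear in remaining mass).
* Supersaturation clamp 500/h above the cap; tests allow 10% headroom at
  the cap.
* Zero dose, zero permeability, all-zero concentration profiles and
  non-estimable terminal slopes all return defined results or flagged
  `NA`s, never fabricated numbers.
* Tmax ties break to the earliest time; the pH ≥ 4 threshold is inclusive;
  bootstrap CIs (2000 resamples) are seeded and scale-invariant.
* `fit_pd_params` flags non-convergence in its return value instead of
  raising, so population fitting loops can triage.

## What the synthetic data do and do not show

The synthetic observed datasets reproduce the *structure* of the clinical
data (sample size, schedule, proportional error, LLOQ censoring) with this
package's own model as truth. Green tests therefore demonstrate that the
pipeline is self-consistent — NCA recovers generating exposure, PD fitting
recovers generating parameters, ratios detect agreement and disagreement —
not that the model reproduces the clinical trial, which would require the
unpublished population library and PD parameters of the original study.
Absolute exposure in this implementation is lower than the original
model's published predictions (see Disposition); directionally the model
reproduces the published food effect and the feedback-driven pH dynamics,
and the printed-arithmetic checks (permeability table, verification
ratios, percent changes) are exact.

## Known limitations

* No enterohepatic recirculation, gut-wall metabolism, or transporter
  efflux (justified by the efflux ratio < 2).
* No food effect inside the PD model itself (meal effects enter through
  physiology only).
* M1 contributes no acid suppression (no human potency data).
* Independent log-normal variability without covariance; baseline pH
  variability off by default.
* The additional systemic clearance's anatomical site is an assumption
  (venous blood).
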