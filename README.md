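# tegopbpk

A coupled physiologically based pharmacokinetic / pharmacodynamic (PBPK/PD)
simulator for **tegoprazan**, a potassium-competitive acid blocker (P-CAB),
and its major metabolite **M1**. The package is aimed at pharmacometricians
and DMPK scientists who want an open, testable implementation of the full
chain from in-vitro assay tables to population predictions of plasma
exposure and intragastric pH.

## What it implements

**In-vitro parameter derivation.** Substrate-depletion regression for
microsomal and recombinant-CYP intrinsic clearance
(`CLint = k / C_protein`; `CLint,rCYP = (0.693/t½)·(1400/pmol CYP)`), and
Caco-2 bidirectional permeability
(`Papp = transport rate / (C_donor · area)`) with efflux ratio.

**Absorption.** A nine-segment compartmental absorption–transit model
(stomach, duodenum, jejunum I–II, ileum I–IV, colon) with
diffusion-layer-model (Nernst–Brunner) dissolution of monodisperse
shrinking spheres,

```
dM/dt = −(3 D M)/(ρ r h) · (S(pH) − C_bulk),   h = min(r, 30 µm)
```

pH-dependent solubility of the weak base (log-linear interpolation through
223 mg/mL at pH 1, 0.7 mg/mL at pH 3, 0.02 mg/mL at pH 6.8), supersaturation
cap and first-order precipitation.

**Disposition.** Full perfusion-limited PBPK for the parent
(`V_t dC_t/dt = Q_t (C_art − C_t·(B/P)/Kp_t)`) with Rodgers–Rowland tissue
partitioning and a global Kp scalar calibrated by bisection so that
Vss = 1.0 L/kg; IVIVE of hepatic clearance through CYP abundances, MPPGL and
liver mass; renal, biliary and additional systemic clearances. M1 uses a
minimal PBPK model: a central compartment plus a single adjusting
compartment (SAC, `dA_sac/dt = k_in·C·V_sac·BW − k_out·A_sac`) and
whole-organ metabolic clearance scaled from HLM + HLC intrinsic clearance.

**Gastric-pH pharmacodynamics.** A sixth-order Fourier-series circadian
baseline, a sigmoid-Emax indirect-response model driven by plasma
tegoprazan,

```
Effect = Base(t) · (1 + Emax·Cp^γ / (EC50^γ + Cp^γ)),   dR/dt = k_in·Effect − k_out·R
```

and a feedback loop: the pH response is written back into the gastric
compartment, where it controls the dissolution of the weak base. Everything
is integrated as one monolithic stiff ODE system (`deSolve::lsoda`).

**Verification statistics.** Non-compartmental analysis
(linear-up/log-down trapezoid, best-adjusted-R² terminal slope),
predicted/observed ratio reports with bootstrap CIs and the 0.7–1.3
acceptance window, and percent-change comparisons.

**Synthetic observed data.** A generator that emulates the clinical study
structure (12 subjects, single 100 mg dose, the clinical sampling schedule,
proportional residual error, LLOQ censoring) so the whole pipeline is
testable without any external data.

## Worked example

```r
library(tegopbpk)

r <- simulate_subject(regimen = dosing_regimen(100, 0))  # 100 mg, fasted
print(r)
w <- r$time <= 24
print(nca(r$time[w], r$cp_parent[w], dose_mg = 100))
holding_rate(r$time, r$gastric_ph)
```

prints

```
Coupled PBPK/PD simulation
  regimen: 100 mg at t = 0 h (fasted)
  horizon: 48.0 h at 0.0833 h resolution
  parent Cmax: 434.5 ng/mL; M1 Cmax: 145.2 ng/mL
  mass-balance residual: 5.8e-15 (parent), 3e-15 (M1)
NCA: AUC0-t 890.1 ng*h/mL | AUCinf 893.3 | Cmax 434.5 ng/mL | Tmax 0.417 h | CL/F 111.9 L/h | t1/2 3.67 h
[1] 69.3
```

The reference subject absorbs the dose quickly (Tmax 0.42 h), eliminates it
with a 3.7 h half-life, and holds intragastric pH ≥ 4 for 69% of the first
24 h; the mass-balance residual confirms the solver conserves drug to
machine precision. Population behavior (5th–95th percentile bands,
holding-rate summaries) comes from `sample_population()` +
`simulate_population()`, or `run_scenario("single_100" | "qd7_100" |
"fast_50" | "fed_50")` for the four study scenarios.

The shipped model configuration (all compound, metabolite, formulation and
PD parameters) is `inst/extdata/tegoprazan.yaml`, loaded with
`load_model_config()`.

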