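---
title: "Cross-cell-type regression from heterogeneous myocyte populations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-cell-type regression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Drug screening platforms built on iPSC-derived cardiomyocytes (iPSC-CMs)
measure electrophysiology in cells whose phenotype differs quantitatively
from adult ventricular myocytes: iPSC-CMs beat spontaneously, have a less
negative diastolic potential, different current densities, and respond
differently to block of the same ion channel. `crosscell` implements a
population-based statistical translation between cell types: heterogeneous
populations of two mechanistic cell models are simulated under a panel of
experimental conditions, biomarkers are extracted from the action
potential (AP) and Ca2+ transient (CaT) of every cell, and a partial least
squares regression (PLSR) is fitted that maps the source cell type's
biomarkers to the target cell type's. The fitted coefficient matrix
(`B_cross`) then translates drug-induced changes measured in the source
cells into predicted changes in the target cells.

The same machinery supports three further analyses: population-based
parameter sensitivity coefficients; ranking of experimental conditions by
how much predictive information they add; and an in silico pharmacology
layer in which drugs are concentration-dependent pore blockers of one to
five ion-transport pathways.

## Heterogeneous populations

Cell-to-cell variability is modelled by multiplying the 13 maximal-rate
ion-transport parameters

GNa, GK1, GKr, GKs, Gto, GCaL, KNCX, KNaK, GpCa, GbNa, GbCa, KRyR, KSERCA

by independent log-normal scale factors with log-mean 0 and log-SD
`sigma_log = 0.2624` (default), which places 95% of expression levels
between 60% and 167% of control. The same scale-factor table is applied to
both cell types, so cell *i* of the source population and cell *i* of the
target population carry identical relative expression profiles — this
index pairing is what makes the regression a *translation* rather than a
correlation of unrelated ensembles.

```{r}
library(crosscell)
sf <- draw_scale_factors(population_config(600, seed = 1))
pops <- build_paired_populations(fixture_model("adult"),
                                 fixture_model("ipsc"), sf)
```

## The fixture cell models

Two reduced cell models ship with the package. They share a single
formulation — nine states: membrane potential `V`; gates `h` (INa
inactivation), `d`, `f` (ICaL activation / voltage inactivation), `r`
(Ito inactivation), `xr`, `xs` (delayed-rectifier activation); cytosolic
`Cai` and SR `CaSR` — and differ only in parameter values. The membrane
currents are Hodgkin–Huxley-type: INa with instantaneous cubic
activation; ICaL with a Goldman–Hodgkin–Katz driving force (hence linear
sensitivity to extracellular Ca2+) and Ca2+-dependent inactivation; IKr
with inward rectification; IKs; Ito; IK1 with a sqrt(Ko) conductance
factor; a Luo–Rudy-form Na+/Ca2+ exchanger; a saturating Na+/K+ pump;
sarcolemmal Ca2+ pump and background Na+/Ca2+ currents. Ca2+ cycling is a
two-compartment system with a Hill-type SERCA uptake flux, an
activation-gated SR release flux and a small leak, with instantaneous
cytosolic and SR buffering. Intracellular Na+ and K+ are held fixed, so
Ca2+ cycling is the only slow process and every protocol converges to its
periodic steady state within a few beats — a deliberate property, because
population studies integrate tens of thousands of protocol instances.

* The **adult-like** fixture rests near −87 mV and, paced at 1 Hz, has an
  APD90 of ≈230 ms, inside the 200–350 ms adult range. APD90 is monotone
  decreasing in the GKr multiplier and CaT amplitude is monotone
  increasing in GCaL, so channel-block pharmacology behaves in the
  physiologically expected direction.
* The **iPSC-like** fixture has a small IK1 and a larger background Na+
  current; the resulting diastolic depolarisation produces spontaneous
  activity at ≈0.9 Hz with a maximum diastolic potential of ≈−78 mV,
  and longer, slower APs than the adult fixture.

These are deliberately reduced models: they reproduce the *structure* of
the problem (13 shared pathways, paced and spontaneous phenotypes,
condition-dependent biomarker shifts) but not the detailed kinetics of
published adult or iPSC models. Any model exposing the same contract —
13 named transport parameters, settable extracellular concentrations, a
deterministic right-hand side — can be plugged in behind the same
interface.

## Protocols and steady state

`standard_protocols()` builds the ten simulated experimental conditions:
the cell-kind baseline (1 Hz pacing for adult-like cells, spontaneous
beating for iPSC-like cells), 0.5 / 1 / 2 Hz pacing, and raised/lowered
extracellular Ca2+ (3.0 / 0.9 vs 1.8 mM), Na+ (300 / 70 vs 151 mM) and
K+ (10 / 3 vs 5.4 mM). Ion overrides are applied as an instantaneous
solution change at t = 0; for iPSC-like cells the ion protocols run in
spontaneous mode. The default duration is 120 s, with the last AP and CaT
recorded.

Integration uses an adaptive embedded Dormand–Prince 5(4) scheme
implemented in C++ (relative tolerance 1e-6, absolute 1e-8, maximum step
2 ms), with the rectangular stimulus (1.5× diastolic threshold: 33 uA/uF
for 2 ms, configurable) represented exactly by splitting the integration
at stimulus edges. The fixture models' rate constants are bounded (no
time constant below ≈0.8 ms), so the explicit adaptive method resolves
them accurately; the packaged integrator is cross-checked against
`deSolve::lsoda` on the same equations in the test suite, agreeing to
within 0.5 mV over multi-beat traces. A step-size collapse marks the
trace as failed instead of raising an error, so population runs continue
and failed cells are flagged.

Because the fixtures equilibrate quickly, the package's own studies use
30 s per protocol for population feature extraction and 15 s for the drug
panel, and *verify* convergence rather than assume it: the steady-state
diagnostic (APD90 of the final two beats differing by <1%) must hold for
at least 95% of paced target cells, and is reported for every paced
condition. With slower models the duration should be raised back to the
120 s default.

## Biomarkers

`extract_features()` computes, from the segmented final beat: APD at
−60 mV (total time above −60 mV within the beat), APD90, APD50 (time from
the upstroke — maximum dV/dt — to 90% / 50% repolarisation of the
peak-to-rest amplitude, linearly interpolated at threshold crossings),
peak and resting voltage (stimulus-onset voltage for paced beats, maximum
diastolic potential for spontaneous ones), CaT amplitude, diastolic and
peak Ca2+, CaT durations at 50% and 90% return toward the within-beat
baseline (measured from the Ca2+ 10%-rise time), the e-fold CaT decay
time measured from the Ca2+ peak, and — for spontaneous recordings — the
beating rate. Conventions that the biomarker names leave open (the start
reference of the CaT durations, the baseline of the e-fold decay) are
fixed as just stated and verified against closed forms on triangular-AP
and exponential-CaT fixtures in the tests.

Cells with abnormal dynamics are flagged by three detectors, all pure
functions of the beat: repolarisation failure (voltage never returns
below −60 mV after the upstroke), afterdepolarisation (a ≥2 mV
depolarising excursion between 50% and 90% repolarisation), and no-beat
(peak-to-rest amplitude <30 mV). A condition is dropped from the analysis
when *strictly more than* 25% of cells are abnormal under it. With the
fixture models, 600-cell populations drop the low-Na+ condition (low
extracellular Na+ suppresses the inward NCX/background-Na+ drive and
spontaneous beating stops in about half the population) and the high-K+
condition (the depolarised diastolic potential inactivates the upstroke
currents in just over a quarter of cells), leaving eight retained
conditions. Whole conditions are dropped; individual flagged cells
elsewhere merely get missing features and contribute no regression row.

## The regression model

`fit_crosscell(x, y)` fits the translation. Features that are strictly
positive (durations, Ca2+ levels, amplitudes, rates) are log-transformed;
voltages (which can be negative) are left on their natural scale; all
columns are then z-scored. The coefficient matrix is estimated by SIMPLS
with a deterministic sign convention, and the number of latent components
is selected by k-fold cross-validation (default five folds — 120-cell
folds for 600-cell populations — with seeded fold assignment): PRESS, the
summed squared held-out residuals on the preprocessed scale, is computed
for each component count, and the smallest count whose PRESS is within 5%
of the minimum is chosen. The per-output R² reported by the fit is
computed from the pooled held-out predictions on the original feature
scale, so it is an honest out-of-sample quantity; `adjusted_r2()` adjusts
it for the selected number of components (the component count, not the
raw predictor count, plays the role of *p*).

Drug-induced changes translate linearly on the preprocessed scale:
`predict(fit, changes, type = "change")` takes log-ratios (post/pre) of
the source features — absolute differences for voltage features — and
returns percent changes of the target features (mV differences for
voltages). Because the map is linear, multiplicative feature changes
compose, and a zero change vector predicts exactly zero change.

Population sensitivity coefficients (`compute_sensitivities()`) regress
log-outputs on log-scale-factors with the same PLSR machinery at full
rank; the coefficients are local power-law exponents (elasticities), and
on synthetic power-law populations the recovery error is below 0.02.

## Ranking experimental conditions

`rank_protocols()` implements both greedy directions — sequential
inclusion (add the condition that raises the mean cross-validated R²
across all target features most) and sequential exclusion (repeatedly
remove the condition whose loss hurts least) — and always produces a full
ranking; users truncate it themselves. `enumerate_triplets()` fits and
cross-validates one model per 3-subset of the candidate conditions (56
models for 8 candidates) and reports per-output adjusted R², sortable to
reproduce the "models containing mostly-informative conditions beat
models containing mostly-uninformative ones" contrast. The mean across
predicted features is unweighted; the baseline spontaneous condition is a
candidate like any other.

## Pharmacology

A drug is a set of 1–5 (pathway, IC50) targets plus a concentration; the
pore-block model leaves the fraction IC50/(IC50+[C]) of each targeted
conductance. There is no state-dependent binding: a drug is a static
multiplier set that composes multiplicatively with the population scale
factors. `hypothetical_drug_library()` builds the 90 two-target drugs (one
per ordered pair of 10 pathways, secondary IC50 = e × primary, simulated
at the lower IC50, i.e. 50%/27% block); `load_drug_catalog()` reads
multi-target drugs from CSV and defaults the concentration to the lowest
IC50 in the row. `simulate_drug_panel()` evaluates a drug list on paired
100-cell populations: per-cell change vectors from the source population
are translated by the fitted model and compared against directly
simulated target changes, with abnormal cells excluded from the summary
(and counted). The across-drug accuracy measure is the identity-line
coefficient of determination, 1 − SS(pred − obs)/SS(obs − mean), which is
the natural score when a perfect predictor must lie on the identity; it
can be negative for a badly biased estimator.

## Problem sizes and reproducibility

The packaged studies (test suite and `scripts/acceptance.R`) use the
study conditions stated above — 600-cell paired populations with
`sigma_log` 0.2624, five-fold CV, the 90-drug panel on 100-cell groups —
with 30 s (populations) and 15 s (panel) protocol durations, which the
steady-state diagnostic validates for the fixture models. On one CPU the
full population study takes roughly two minutes and the drug panel about
ten. Every random step (scale-factor draws, fold assignment) is seeded
explicitly, seeds are recorded in the artifacts, and repeated runs are
bit-identical.

## Known limitations

* The fixture models are reduced: quantitative biomarker values (e.g.
  CaT amplitudes) are stylised, and the package's high cross-validated R²
  partly reflects the structural similarity of the two fixtures. The
  claim the tests support is that the pipeline recovers the translation
  when one exists and ranks conditions correctly — not that any
  particular R² would be obtained with detailed published models.
* Pore block is concentration-static; use-dependent or state-dependent
  drugs are out of scope.
* Only maximal rates are randomised; kinetic parameters are shared across
  the population.
* The K+-override conditions can interact strongly with the automaticity
  mechanism of spontaneous models; the abnormality rule handles this, but
  users plugging in other models should inspect the abnormality report
  rather than assume the fixture behaviour.
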