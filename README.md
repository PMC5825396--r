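# crosscell

Quantitative translation of cardiac drug responses across cell types from
simulated heterogeneous myocyte populations.

## The problem

Cardiomyocytes derived from induced pluripotent stem cells (iPSC-CMs) are
a practical screening platform for cardiac drug effects, but their
physiology is immature: they beat spontaneously, rest at a less negative
potential, and respond to ion-channel block quantitatively differently
from adult ventricular myocytes. A drug that prolongs the iPSC-CM action
potential by 30% will generally not prolong the adult action potential by
30%.

`crosscell` addresses this with population-based cross-cell-type
regression. Heterogeneous populations of two mechanistic cell models are
generated by multiplying 13 ion-transport parameters (G_Na, G_K1, G_Kr,
G_Ks, G_to, G_CaL, K_NCX, K_NaK, G_pCa, G_bNa, G_bCa, K_RyR, K_SERCA) by
log-normal scale factors (log-SD 0.2624, i.e. 95% of expression between
60% and 167% of control), with the *same* scale factors applied to both
cell types. Each cell is simulated under a panel of experimental
conditions (spontaneous activity, 0.5/1/2 Hz pacing, raised/lowered
extracellular Ca2+, Na+, K+), and 11–12 biomarkers are extracted per
condition from the action potential and Ca2+ transient (APD at -60 mV,
APD90, APD50, V_peak, V_rest, CaT amplitude, diastolic/peak Ca2+, CaT
durations, e-fold decay time, beating rate). Partial least squares
regression (SIMPLS, with PRESS-based cross-validated component selection)
then yields a coefficient matrix **B_cross** mapping source-cell
biomarkers to target-cell biomarkers:

    y_target = f_y^-1( f_x(x_source) %*% B_cross )

where f_x, f_y log-transform positive features and z-score everything.
Drug-induced changes (log-ratios of features before/after drug) translate
through the same linear map and are reported as percent changes. Drugs
are modelled as pore blockers: each targeted conductance is multiplied by
IC50/(IC50+[C]).

Two reduced fixture cell models ship with the package (an
adult-ventricular-like paced cell and a spontaneously beating iPSC-like
cell sharing all 13 pathways); any model exposing the same contract can
be plugged in.

## Worked example

```r
library(crosscell)

# paired 120-cell populations of the two fixture cell types
sf  <- draw_scale_factors(population_config(120, seed = 3))
src <- simulate_population(fixture_model("ipsc"),
                           standard_protocols("ipsc", duration = 30),
                           scale_factors = sf)
tgt <- simulate_population(fixture_model("adult"),
                           standard_protocols("adult", duration = 30)["pace1"],
                           scale_factors = sf, steady_check = TRUE)
print(src$abnormal[, c("protocol", "fraction", "drop")])

# fit the cross-cell model on the retained conditions
fit <- fit_crosscell(retained_features(src),
                     feature_table(tgt$features), seed = 3)
summary(fit)
```

Output from this run:

```
   protocol    fraction  drop
      spont 0.016666667 FALSE
    pace0.5 0.066666667 FALSE
      pace1 0.008333333 FALSE
      pace2 0.000000000 FALSE
     CaHigh 0.108333333 FALSE
      CaLow 0.016666667 FALSE
     NaHigh 0.008333333 FALSE
      NaLow 0.508333333  TRUE
      KHigh 0.208333333 FALSE
       KLow 0.008333333 FALSE

Cross-cell-type PLSR model: 95 cells, 14 components
Held-out R2 by target feature:
           feature     r2 adj_r2
      pace1.APDm60 0.9838 0.9810
       pace1.APD90 0.9837 0.9808
       pace1.APD50 0.9919 0.9905
       pace1.Vpeak 0.6829 0.6274
       pace1.Vrest 0.5660 0.4900
        pace1.CaTA 0.9688 0.9634
     pace1.Ca_rest 0.9673 0.9616
     pace1.Ca_peak 0.9687 0.9632
       pace1.CaD50 0.9855 0.9830
 pace1.CaDecayTime 0.9479 0.9387
       pace1.CaD90 0.9846 0.9819
```

Reading this: under low extracellular Na+ half the spontaneous iPSC-like
cells stop beating, so that condition is dropped by the >25%-abnormal
rule; the model fitted on the remaining conditions predicts adult APD90
and CaT amplitude with held-out R-squared of 0.98 and 0.97 — the
cross-validated accuracy of the translation, not a training fit. Cells
flagged abnormal anywhere contribute no row (120 - 25 = 95 used).

To translate a drug effect, build the change vector and predict:

```r
chg  <- feature_change(fit, pre = x_before, post = x_after)
pred <- predict(fit, chg, type = "change")   # percent changes in the adult cell
```

`rank_protocols()` / `enumerate_triplets()` rank the experimental
conditions by predictive information, and `simulate_drug_panel()`
evaluates a drug library (e.g. `hypothetical_drug_library()`, 90
two-target pore blockers) on paired 100-cell populations, comparing the
cross-model prediction against the naive direct readout. A thin CLI over
the same functions is in `inst/cli/crosscell.R`
(`Rscript inst/cli/crosscell.R --help`).

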