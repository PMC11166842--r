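# allocamp

Kinetic modelling of allosteric modulation of CB1-mediated cAMP signalling.

## The problem

The cannabinoid CB1 receptor inhibits forskolin-stimulated cAMP production.
The allosteric modulator ORG27569 raises orthosteric agonist affinity yet
blocks G-protein signalling, and in real-time CAMYEL BRET assays this
produces a *kinetic lag*: cAMP inhibition by an agonist such as CP55940
looks normal for several minutes after modulator addition, then is
progressively lost, often ending in inverse agonism (cAMP above the
forskolin-alone level). `allocamp` is for pharmacologists and modellers who
want to simulate this system, quantify the lag, propagate parameter
uncertainty into prediction bands, and explore probe dependence across
agonists — with a synthetic plate-data generator so the whole pipeline is
testable without any raw data.

## The model

Receptor species (fractions of `R0 = 1`): free constitutively active `R`,
agonist-bound `AR`, a transitional ternary complex `ARB_T` that cannot
signal but still internalises, the inactive ternary complex `ARB`, and the
modulator-bound free receptor `RB`:

```
A + R  <-> AR          kon_A, koff_A = kon_A * 10^(6 - pKd)
B + AR <-> ARB_T       kon3, koff3
ARB_T  <-> ARB         k_TI, equilibrium ratio K_TI_eq
B + R  <-> RB          kon2, koff2 = kon2 * Kd_B
AR, ARB_T -> R_lost    k_int, k_int_T   (internalisation)
```

Only `R` and `AR` signal. Their combined signal `I = eps_R*R + eps*AR`
(`eps = 10^1.66 ≈ 45.7` for CP55940) suppresses cAMP through an EMAX model:

```
dC/dt = k_in * (1 - Imax * I / (I50 + I)) - k_out * C     (forskolin on)
```

with cAMP normalised so the receptor-free forskolin steady state is 1.
Because `eps` is large, 10% occupancy already gives 82% inhibition
(receptor reserve) — the lag ends when `AR` drops below that threshold.
The default simulator is the quasi-equilibrium reduction (lumping
`ARB` with `ARB_T` and `RB` with `R`); the full mass-action system is
available with `method = "full"`.

The lag statistic `T_d` is computed two ways, matching practice: the
model rule (first time the ORG-minus-control difference exceeds a 0.01
tolerance) and the empirical rule (fit a plateau-followed-by-one-phase
association to the subtracted curve and solve the crossing in closed form).

## Worked example

```r
library(allocamp)
p <- reference_parameters()          # CP55940 + ORG27569 reference set

# kinetic lag: 1 uM CP55940 + 100 nM ORG27569 vs CP55940 alone
with_b    <- observe_trace(simulate_timecourse(p, standard_schedule(1, 0.1, horizon = 30)))
without_b <- observe_trace(simulate_timecourse(p, standard_schedule(1, 0,   horizon = 30)))
model_lag(with_b, without_b, tolerance = 0.01)
#> kinetic lag (model): T_S = 14.503 min, T_d = 14.503 min (tolerance 0.01)

# probe dependence at 1 uM modulator
compare_profiles(c("CP", "WIN", "THC_calibrated"),
                 standard_schedule(1, 1, horizon = 30), grid_step = 0.2)
#>          agonist       T_S       T_d separated inverse_agonism error
#> 1             CP  4.980346  4.980346      TRUE            TRUE  <NA>
#> 2            WIN  8.412782  8.412782      TRUE           FALSE  <NA>
#> 3 THC_calibrated 11.352264 11.352264      TRUE           FALSE  <NA>
```

At 100 nM modulator the curves separate after ~14.5 min — the hallmark
~15-min lag. At 1 µM modulator the reference agonist lags ~5 min and ends
in inverse agonism; the high-efficacy agonist WIN55,212-2 lags longer and
shows none (its receptor reserve is deeper), and THC with the calibrated
ten-fold-lower modulator association rate (`kon3 = 0.05`) lags longer
still with no inverse agonism — the probe-dependence signature.

Other entry points: `sample_parameters()` / `prediction_band()` /
`coverage_report()` for uncertainty propagation, `generate_dataset()` /
`preset_design()` for synthetic plates, `calibrate_kon3()` for grid
calibration of the modulator association rate, and `run_pipeline()` for
config-driven runs that write CSV/JSON artifacts plus a reproducibility
manifest. The methods vignette (`vignettes/allocamp-methods.Rmd`) explains
the model, the calibration of unprinted rates and the design choices.

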