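# kinrace

Kinetic-race analysis of kinesin processivity: turn single-molecule motility
observables — run lengths, microtubule dwell times, stopped-flow observed
rates, pelleting affinities — into chemomechanical cycle rate constants.

It is written for single-molecule biophysicists analyzing processive motor
data (kinesin-1/kinesin-3 dimers in particular) who want the standard race
algebra, the censored-distribution fitting, and the electrostatics
bookkeeping in one tested place, together with a seeded simulator of the
stepping cycle so every estimator can be validated without instrument data.

## The model

Each stepping cycle of a dimeric kinesin passes through a vulnerable
one-head-bound state that resolves either by the tethered head attaching to
the next tubulin site (rate k<sub>on</sub><sup>TH</sup>) or by the bound
head detaching (rate k<sub>detach</sub>). The per-cycle detachment
probability is

    p_detach = k_detach / (k_onTH + k_detach)  ≈  k_detach / k_onTH

so the run length in 8-nm steps is 1/p_detach, and inverting,

    k_onTH = k_off × RL_steps

with k<sub>off</sub> measured as the reciprocal ADP dwell time. A second
decomposition, K<sub>D</sub> = k<sub>detach</sub>/k<sub>on</sub><sup>Mt</sup>,
recovers the detachment rate from a pelleting affinity and a stopped-flow
bimolecular on-rate. The package implements this algebra with 95% CIs
propagated by relative-error quadrature and a strict unit algebra, plus:

- a Monte-Carlo simulator of the stepping cycle (geometric step counts,
  exponential cycle times) with pixel/frame detection censoring;
- left-truncated single/double exponential maximum-likelihood fits,
  Michaelis–Menten, Langmuir-isotherm and (weighted) linear fits, segmented
  velocity, survival curves;
- peptide net-charge at pH 6.9, the loop-12 (K-loop) charge ledger, ionic
  strength and Debye-length arithmetic, and buffer presets.

## Worked example

```r
library(kinrace)

measurements <- data.frame(
  construct     = c("1A_393", "1A-K1L12", "Kin1", "K1-1AL12"),
  dwell_s       = c(1.8, 0.3, 1.5, 1.4),
  dwell_ci      = c(0.08, 0.03, 0.1, 0.1),
  run_length_um = c(3.0, 0.5, 0.8, 0.9),
  run_length_ci = c(0.02, 0.004, 0.02, 0.02))
run_race_report(measurements)$rendered
#>  construct     dwell    off_rate   steps   kon_th error
#>     1A_393 1.8 ± 0.1 0.56 ± 0.02 375 ± 3  208 ± 9  <NA>
#>   1A-K1L12 0.3 ± 0.0 3.33 ± 0.33  63 ± 1 208 ± 21  <NA>
#>       Kin1 1.5 ± 0.1 0.67 ± 0.04 100 ± 3   67 ± 5  <NA>
#>   K1-1AL12 1.4 ± 0.1 0.71 ± 0.05 113 ± 3   80 ± 6  <NA>
```

Reading: despite a 6-fold run-length difference, the two KIF1A-based
constructs share a tethered-head attachment rate of ~208 s⁻¹ — the
lysine-rich K-loop controls processivity through the detachment rate, not
through tethered-head attachment — while the kinesin-1 backbones attach
roughly 3-fold slower (67–80 s⁻¹), consistent with their slower stepping.

Round trip through the simulator (run as `analysis/02_simulation_roundtrip.R`):

```
Simulated 10000 runs; 567 (5.7%) fell below the 0.17-um censor.
Fitted run length: 2.92 +/- 0.06 um (race prediction 2.97 um).
Recovered k_on_TH: 205 +/- 4 s^-1 (true 208 s^-1).
```

The `analysis/` directory holds the four numbered drivers (race table,
simulation round trip, binding-kinetics fits, charge regression); each
prints its findings and writes tables under `results/`.

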