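---
title: "Methods: the kinetic race behind kinesin processivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the kinetic race behind kinesin processivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinrace)
```

## The model

A processive kinesin dimer steps along a microtubule until it detaches. After
ATP hydrolysis the motor occupies a vulnerable one-head-bound (1HB) state
that resolves in one of two ways: the tethered head binds the next tubulin
site (rate $k_{on}^{TH}$, completing an 8-nm step) or the bound head detaches
(rate $k_{detach}$, ending the run). Because the two transitions compete
within every cycle, the per-cycle detachment probability is

$$p_{detach} = \frac{k_{detach}}{k_{on}^{TH} + k_{detach}}
  \approx \frac{k_{detach}}{k_{on}^{TH}},$$

the number of steps per run is geometric with mean $1/p_{detach}$, and the
run length is that step count times the step size. Inverting the race gives
the experimentally useful identity

$$k_{on}^{TH} = k_{off} \times RL_{steps},$$

where $k_{off}$ is the off-rate measured in saturating ADP (the nucleotide
state that mimics the vulnerable 1HB state) and $RL_{steps}$ is the ATP run
length divided by 8 nm. `detach_probability()`, `run_length_in_steps_from_p()`,
`off_rate_from_dwell()`, `steps_from_run_length()` and
`tethered_head_on_rate()` implement this algebra; `race_table()` applies it
row-wise to per-construct measurements. Both the exact and the approximate
("$\approx$") forms of $p_{detach}$ are exposed behind a flag, defaulting to
exact; they differ by a relative factor of at most $p_{detach}$ itself.

A second, independent decomposition uses solution biochemistry: the
dissociation constant factors as $K_D = k_{detach}/k_{on}^{Mt}$, so a
pelleting-assay $K_D$ times a stopped-flow bimolecular on-rate yields the
detachment rate (`detach_rate_from_affinity()`). The printed WT and loop-swap
detachment rates (18 and 66 s$^{-1}$) are reproduced by the ATP-column $K_D$
values (1.7 and 7.2 µM); the ADP-column values (1.3 and 5.1 µM) give 13.8 and
46 s$^{-1}$. The function computes from whichever $K_D$ the caller supplies
and takes no position on which pairing is intended; the worked analyses use
the values that reproduce the published rates.

## Uncertainty propagation

All measured quantities are "fit ± 95% CI". No propagation formula is
standard-issue for such tables, so the package adopts first-order
relative-error quadrature with symmetric intervals: for products, quotients
and reciprocals the relative CI of the result is the root sum of squares of
the inputs' relative CIs. This is implemented once, in the `rate_estimate`
container, together with a unit algebra over
{s, µM, µm} exponents — multiplying micromolar by per-micromolar-per-second
yields per-second; any combination that leaves the tagged unit set raises an
error rather than producing an untagged number. Quadrature reproduces the
published step-count CIs exactly and the attachment-rate CIs for two of the
four constructs; for the other two the published CIs are 1–2 units tighter
than quadrature from full precision, consistent with propagation from the
*rounded displayed* values — since no single convention matches all rows, the
package keeps full-precision quadrature and treats rounding purely as a
render-time concern (`format_race_table()`, half-up, matching the published
62.5 → 63 and 112.5 → 113).

## The synthetic-data generator

`simulate_processive_runs()` draws the stepping cycle directly: step counts
are geometric with success probability $p_{detach}$ (support includes 0 — a
motor may detach before its first resolved step; such events are invisible
below the pixel censor, exactly as in real kymographs), run length is
`n_steps × 8 nm`, and run duration is the sum of `n_steps + 1` exponential
cycle times at the overall stepping rate `k_step` (212 s$^{-1}$, i.e.
1.7 µm/s over 8-nm steps). The exponential total-cycle-time model is a
deliberate simplification: only the mean velocity of runs is ever compared,
so no sub-state kinetic partition is invented. Dwell times come from
single- or two-component exponential mixtures (`dwell_mixture()`,
`simulate_dwell_times()`); the loop-swap ADP mixture is generated at the
fast/slow weights of roughly 40%/60% reported in the text (the accompanying
figure legend says "equal weights"; the generator accepts either).

Detection censoring mirrors the imaging analysis: traces under 3 pixels
along the distance axis (ATP run lengths) or 3 frames along the time axis
(ADP dwells) are removed. The default pixel size, 0.0567 µm, is chosen so
the 3-pixel cutoff is 0.17 µm; frame intervals of 0.1, 0.02 and 0.2 s
correspond to the 10, 50 and 5 fps acquisition settings. Curve generators
(`simulate_bimolecular_rates()`, `simulate_half_site_release()`,
`simulate_pelleting()`) add Gaussian noise to exact closed-form curves —
mean ± SEM points justify an additive model — and are exact when
`noise_sd = 0`; pelleting fractions are clipped at zero and may exceed 1
because they are normalized to an AMPPNP-bound control.

What the generator does **not** emulate: localization error,
photobleaching, pausing within runs, load dependence of detachment, or any
correlation structure between consecutive cycles. Passing round-trip tests
therefore demonstrates that the estimators are unbiased for the idealized
generating process at realistic sample sizes — not that they are robust to
every artifact of real TIRF data.

All generators take an explicit `seed`, restore the caller's RNG state, and
are byte-reproducible; the pipeline derives per-stage substreams from one
root seed.

## Estimators and numerical choices

**Truncated exponential MLE.** Run-length and dwell distributions are fit
above the detection cutoff. For an exponential left-truncated at $c$,
memorylessness makes the MLE the mean excess, $\hat\tau = \overline{x - c}$
over $x \ge c$, with CI $1.96\,\hat\tau/\sqrt{n}$. This estimator is
shift-equivariant by construction (fitting $\{x\}$ at cutoff $c$ equals
fitting $\{x+d\}$ at $c+d$), which the tests verify exactly. A
least-squares-on-log-survival route is available through
`empirical_survival()` plus `fit_linear()` and agrees within CI on clean
data.

**Biexponential EM.** Two-component fits shift the retained samples by the
cutoff, run EM for a two-exponential mixture from a fixed ladder of
quantile-based starts (deterministic, no RNG), pick the best log-likelihood,
and then correct the weights back to the untruncated population by undoing
the $e^{-c/\tau_j}$ truncation reweighting. Components are reported
$\tau_1 < \tau_2$ with weights summing to 1. A fit is flagged
near-degenerate when $\tau_1/\tau_2 > 0.9$, when a component is starved
(truncated weight < 2%), or when the mixture fails a likelihood-ratio test
against the single-exponential fit at the $\chi^2_2$ 95% point — the last
criterion is what reliably catches genuinely single-exponential data, where
EM can park two well-separated taus on a nearly flat likelihood.

**Saturation and linear fits.** Michaelis–Menten and Langmuir curves are the
same two-parameter model fit by Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`, bounded below at zero, started from the data maximum
and the half-saturation abscissa), with 95% CIs from the asymptotic
covariance; an all-zero response short-circuits to a flagged zero fit.
Linear fits use `stats::lm`, optionally inverse-variance weighted, with
t-based 95% CIs. The charge/run-length regression is unweighted OLS by
default because that reproduces the published low-ionic-strength slope
(2.7 µm per unit charge) exactly; on the three high-ionic-strength points
both weightings give 0.85 versus the published 0.9 ± 0.6 — the package
reports its computed value and checks only sign and CI overlap.

**Segmented velocity.** The published velocities came from manual kymograph
segmentation; here a two-pass automatic procedure stands in: interval speeds
smoothed over a 3-frame window are classified as paused below 0.25× the
trace median speed, contiguous motile stretches are merged (edges trimmed of
sub-threshold intervals), and segments displacing less than 3 pixels are
dropped. This reproduces the one property the analysis uses — segmented
velocity exceeds end-to-end velocity for pausing traces — and is not claimed
to replicate manual tracing decisions.

## Electrostatics

Net charges of loop and coil segments use integer per-residue charges at
pH 6.9 (K/R +1, D/E −1, H neutral at pKa ≈ 6; termini ignored for internal
segments); `charge_model()` accepts overrides. The loop-12 ledger (WT +4
with 6 lysines, SuperK +7, kinesin-1 swap +1, 4Q 0, 5Q −1) ships as packaged
data because the mutant loop sequences are published only graphically;
`validate_charge_ledger()` checks substitution deltas internally and against
user-supplied FASTA sequences when available. Buffer ionic strengths
(184 mM for the 80 mM PIPES buffer, 36 mM for the 12 mM PIPES buffer) are
stored constants from a dedicated speciation calculation; the generic
$I = \tfrac12\sum c_i z_i^2$ and the Debye length
$\lambda_D = \sqrt{\varepsilon_0\varepsilon_r k_B T / (2 N_A e^2 I)}$
(CODATA constants, $\varepsilon_r = 78.5$ at 298.15 K; ≈ 0.304 nm/$\sqrt{I[M]}$)
are computed. The printed 0.7 and 1.6 nm screening lengths follow at one
decimal.

## Problem sizes and reproducibility

The worked analyses and tests use 10,000 simulated runs for round trips
(Monte-Carlo error ≈ 1% on the fitted run-length constant; the acceptance
script uses 100,000 to hold it near 0.3%), 5,000 dwells for biexponential
recovery (both taus within 20%), 200 replicates of 1,000 events for the
noise-robustness property (τ within 10% of truth in ≥ 95% of replicates),
and exact noiseless curves for the saturation and linear fits (recovery to
10⁻⁶ relative error). Every stochastic step takes an explicit seed;
`run_full_pipeline()` is byte-deterministic for a fixed config and seed and
embeds seed, package version and config in its provenance block.

## Known limitations

- The race model treats cycles as independent and identically distributed;
  it cannot represent load dependence, track heterogeneity, or motor
  crowding.
- Quadrature CIs are first-order and symmetric; for ratios with large
  relative error (e.g. the detachment rate from a poorly determined $K_D$)
  they understate asymmetry.
- The biexponential CI estimates use per-component effective counts, not the
  full Fisher information; they are indicative, not exact.
- Histidine is fixed neutral by default; fractional titration charges are
  out of scope, as is buffer speciation chemistry.

```{r example}
report <- run_race_report(data.frame(
  construct = "WT", dwell_s = 1.8, dwell_ci = 0.08,
  run_length_um = 3.0, run_length_ci = 0.02))
report$rendered
```
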