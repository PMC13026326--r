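---
title: "Limiting-component quantification of qPCR curves: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Limiting-component quantification of qPCR curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncopyr)
```

## The model

A qPCR reaction in its exponential phase multiplies the target by the
PCR efficiency `E` (1 < E ≤ 2) each cycle: `N(c) = N0 · E^c`. The phase
ends when one reagent becomes limiting — the primers, or a
non-saturating DNA-binding dye such as SYBR Green I that is itself
consumed by staining product. The end of the exponential phase is
marked by the maximum of the curve's second derivative, located here as
the zero crossing of the third derivative (TD0). Because the molar
amount of the limiting component fixes the number of copies present at
that point, dividing that copy ceiling by `E^TD0` undoes the
amplification and yields the starting copy number:

* primer-limited: `Ncopy = C_p · prim · N_A · vol / 10^15 / E^TD0`
* dye-limited: `Ncopy = C_d · dye · N_A · vol / (amp · 10^15) / E^TD0`

`C_p` and `C_d` are empirical constants capturing which fraction of the
component is effectively committed when TD0 is reached (defaults:
`C_p` 0.1 for hydrolysis probes, 0.04 for saturating dyes; `C_d` 1.5
for SYBR Green I at a default working concentration of 400 nM).
Single-stranded input yields one double-stranded product molecule after
the first cycle where double-stranded input yields two, so Ncopy is
doubled for single-stranded material (the package default; set
`input_strandedness = "double"` for genomic DNA).

Two properties make the approach machine independent. TD0 involves only
differences of the raw signal, so constant and linear baseline
components cancel exactly; and the conversion never uses the absolute
fluorescence scale, only the cycle axis and reagent bookkeeping.

## The per-curve algorithm

1. **Derivatives** (`compute_derivatives()`): central differences for
   the first and second derivative; the second derivative is smoothed
   with a three-cycle moving geometric mean (arithmetic fallback where a
   value is non-positive, where the geometric mean is undefined); the
   third derivative is the unit difference of the smoothed series,
   indexed at half cycles.
2. **TD0** (`call_td0()`): the admissible zero crossing of the third
   derivative must lie within two cycles of the first-derivative
   maximum. Curves whose total rise stays below ten times the robust
   ground-phase cycle-to-cycle scatter are no-calls
   (`no_amplification`), a result rather than an error.
3. **Exponential window** (`find_exponential_phase()`): stop cycle
   `floor(TD0 − 0.5)`; walk backwards while the fluorescence keeps
   decreasing in that direction; exclude the start cycle itself; require
   at least 4 and keep at most the 9 cycles nearest the stop.
4. **Baseline and efficiency** (`estimate_baseline_efficiency()`):
   bisection on the constant baseline within `[0, min(window))`,
   comparing straight-line slopes of the lower and upper halves of the
   log10-transformed window until they agree to 1e-5 (cap 200
   iterations, far below float resolution of the interval);
   `E = 10^slope` of the upper half.
5. **Per-target pooling** (`mean_target_efficiency()`): individual
   efficiencies are noisy; the target mean is used for quantification.
   When the distribution is skewed (|mean − median| > 0.25 SD) a
   two-sided Grubbs test at α = 0.05 removes outliers iteratively, never
   below three values. No-template controls are analyzed but never
   pooled; a called TD0 in an ntc raises a contamination warning.

### Locating the zero crossing to sub-cycle precision

The second-derivative peak of a real amplification curve is only a few
cycles wide, and with once-per-cycle sampling a linear interpolation of
the third-derivative zero inherits a sampling-phase-dependent bias that
we measured at up to 0.4 cycles on noiseless synthetic curves. The
package therefore resamples: a provisional straight ground line is
fitted by least squares to the pre-exponential cycles and subtracted
(a linear fit is exactly equivariant under linear baseline changes, so
the baseline invariance of TD0 survives to machine precision), the
corrected curve around the peak is modelled by a cubic regression
spline in log space — knots on every cycle across the bend, every
second cycle in the log-linear flanks, so flank noise is averaged
rather than interpolated — and the derivative and smoothing stencils
are evaluated densely (0.002-cycle grid) on the model. Among admissible
crossings the one at the global smoothed-second-derivative maximum is
returned. Against a dense continuous oracle this lands within 0.031
cycles on noiseless curves (200-curve suite) while keeping the
replicate scatter at 2% multiplicative noise low enough for
technical-replicate CVs well under the 0.3 quality gate. When the
resampling path is unavailable (non-positive corrected readings, very
short windows) the plain linear chord between the bracketing
third-derivative values is used instead.

Note the efficiency estimation deliberately retains the paper-style
constant-baseline bisection: a constant is the method's stated baseline
model, and raw exports from a stable instrument drift little. Strong
linear drift biases the efficiency low (the troubleshooting signature
is a curve efficiency below the dilution efficiency).

## Experiment-level pipeline

`analyze_experiment()` runs, in order: per-run quantification →
single-standard calibration → inter-run correction → (optionally
geNorm) → reference normalization → replicate QC → group statistics.
Each step is a pure multiplicative rescaling whose factor is reported,
so within-target ratios are never distorted.

* **Calibration** uses the standard with the highest expected amount
  (`std_conc × vol`); at least 6 replicates and 1000–5000 expected
  copies are advised (warnings otherwise).
* **Inter-run correction** fits `log10(Ncopy) = µ(group:target) +
  ρ(run)` by least squares over the (group, target) cells present on
  several plates; factors `10^−ρ` are rescaled to geometric mean one.
  Log space is the natural scale for a multiplicative plate effect and
  makes the estimator robust to unbalanced designs; the procedure is
  idempotent. Runs not connected through shared cells are an error that
  names the components.
* **geNorm** implements the classical stability measure
  `M(j) = mean_k SD_samples(log2 N_j/N_k)` with iterative worst-gene
  removal, and sizes the reference set by the pairwise variation
  `V(n/n+1)` of consecutive normalization factors with the conventional
  0.15 cutoff (configurable). Fewer than 8 samples warns.
* **Normalization** divides each target of interest by the per-sample
  geometric mean of the references and multiplies by the experiment-wide
  reference geometric mean, so normalized values stay interpretable as
  absolute copy numbers.
* **Group statistics**: Welch t / Mann-Whitney for two groups, one-way
  ANOVA / Kruskal-Wallis for more, with Tukey HSD or Dunn-Holm post-hoc
  comparisons only when the omnibus test rejects — avoiding type-I
  accumulation from separate pairwise tests. Fold differences carry
  first-order SEM-propagated errors. One value per biological sample
  (the mean over technical replicates) enters the tests.

## The synthetic test bed

`simulate_run()` generates plates from continuous limiting-component
kinetics,

`dN/dt = N · log(1 + (E0 − 1) · (1 − (N/limit)^k))`,

integrated with `lsoda` at tight tolerance and read once per cycle as
`F(c) = baseline_a + baseline_b·c + scale·N(c)·(1 + ε_c)`,
`ε_c ~ N(0, noise_sd)`. Design choices, with rationale:

* **Exact exponential limit.** For `N ≪ limit` the trajectory is
  exactly `N0·E0^t`, so ground-phase per-cycle ratios equal `E0` and
  dilution spacing is `log(10)/log(E0)` cycles per decade.
* **Saturation sharpness `k` (default 2.5).** With plain linear
  depletion (`k = 1`) the transition is so gradual that the
  third-derivative zero sits more than two cycles below the
  first-derivative maximum, outside the method's search gate, and the
  copy count at TD0 is a small fraction of the ceiling — real reactions
  stop faster. `k = 2.5` reproduces a transition on which the gate and
  the recovery analysis are well-posed across `E0 ∈ [1.85, 2.0]`, the
  efficiency range of well-optimized assays.
* **Ceiling placement.** The analyzer assumes that
  `C·component` copies exist at TD0. The generator therefore puts its
  kinetic ceiling at `limit_copies / φ(E0, k)`, where `φ` is the copy
  fraction reached at the oracle TD0, computed from the continuous model
  itself (scale invariant, no fitted constant). This is the simulated
  analogue of the empirical calibration that produced `C_p`/`C_d`, and
  it makes absolute recovery a meaningful test.
* **Noise and drift defaults** (`noise_sd = 0.02` multiplicative,
  `baseline_b = 0.1` units/cycle against a ~3000-unit plateau) emulate a
  stable modern instrument. Multiplicative noise matches the
  observation that machines report proportionally scaled fluorescence.
* **`run_factor` vs `copy_factor`.** A plate-level optical scale factor
  (`run_factor`) is invisible to the scale-free method — the tests
  confirm Ncopy barely moves under a 3× scale change — so the quantity
  inter-run correction must recover is a plate-level copy bias,
  modelled by `copy_factor`.
* **Determinism.** All randomness flows from explicit integer seeds;
  the caller's RNG stream is preserved.

`oracle_td0()` is the independent reference: it evaluates the same
unit-lag derivative and smoothing stencils with continuous argument on
a dense grid (step 0.001 cycles; halving the step moves the result by
less than 1e-3) of the noise-free trajectory. The package routine only
ever sees the integer-cycle samples, so the two are independent routes
to the same estimand. The raw infinitesimal third derivative is *not*
the estimand — the method is defined through unit-cycle stencils and a
three-cycle smoother, and the two differ by 0.5–1 cycles.

What the simulator does **not** capture: melting-curve artifacts and
primer-dimer signals (reactions can only be pre-flagged via the
`excluded` annotation), probe hydrolysis chemistry, pipetting error
structure beyond i.i.d. noise, optical crosstalk, and inhibitor
effects on efficiency. Passing recovery tests therefore demonstrates
correctness of the algorithms under the stated kinetics, not
performance on every pathological real-world plate.

## Problem sizes and numerical choices

The shipped test suite uses plates of 3–8 wells over 45 cycles,
100–200-curve randomized suites for the invariance and oracle checks,
200 seeds for dilution recovery, 1000 for the type-I-error check, and a
brute-force baseline grid of 1e5–1e6 candidates; the whole suite runs
in well under a minute on one core. Tie-breaks and degenerate inputs:
multiple admissible third-derivative crossings resolve to the one at
the smoothed-second-derivative maximum; `d3 = 0` at a sample counts as
the end of a positive-to-negative crossing; flat or pure-noise curves
are no-calls; a target whose every curve fails analysis gets no mean
efficiency and its reactions are flagged; `n = 2` efficiency values are
averaged without outlier testing; Grubbs stops at `n = 3`.

## Known limitations

* The efficiency estimate carries the exponent: a 0.01 error in `E`
  moves Ncopy by ~15% at TD0 = 28. Absolute accuracy is limited by
  efficiency precision, not by TD0.
* `C_p`/`C_d` are chemistry- and mix-dependent; values for master mixes
  other than the calibrated defaults may need adjustment
  (both are configurable per dye).
* The constant-baseline model biases `E` under strong baseline drift;
  use raw, stable exports.
* Inter-run correction assumes a single multiplicative plate effect;
  position-dependent (edge) effects are out of scope.
* The statistics cover one-way designs only; repeated-measures or
  multi-factor experiments belong in dedicated modelling packages.
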