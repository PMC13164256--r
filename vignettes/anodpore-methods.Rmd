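---
title: "Methods: process-structure surrogates and Renkin-corrected Higuchi release"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: process-structure surrogates and Renkin-corrected Higuchi release}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anodpore)
```

## The modelling problem

Nanoporous anodic alumina (NAA) coatings release a drug loaded into their
cylindrical pores by diffusion, and the pore diameter set during
anodization is the main control parameter. `anodpore` chains two models:

* a **process–structure surrogate** predicting pore diameter (nm) from
  electrolyte type, voltage (V), temperature (°C) and time (min), fitted
  either by ordinary least squares or by a small feed-forward network;
* a **structure–release model** converting a pore diameter into Higuchi
  square-root release kinetics, with the pore-size dependence of the
  diffusivity given by the Renkin hindrance polynomial.

Because multi-study anodization compilations are rarely deposited, the
package also ships a seeded synthetic-data generator that emulates their
statistical structure; every stage of the pipeline is exercised against it
in the test suite.

## The synthetic-data generator

The generator draws, per record, an electrolyte class, then uniform
process inputs over class-appropriate windows, and a pore diameter from a
linear mean model plus Gaussian noise:

d = b0[e] + b_V[e]·V + b_T·T + b_t·t + N(0, σ²)

**Defaults and why.** Voltage windows follow common practice per acid:
sulphuric 15–30 V, oxalic 30–80 V, phosphoric 80–200 V; temperature 0–30
°C; time 10–600 min. Voltage slopes are 1.0, 1.29 and 1.5 nm/V for
sulphuric, oxalic and phosphoric acid — inside the 1.0–1.5 nm/V band
reported across the literature, with the oxalic value equal to the
classical 1.29 nm/V proportionality. The temperature slope defaults to
−0.4 nm/°C (midpoint of the commonly reported −0.3 to −0.5 band) and the
time slope to 0, since anodization time mainly sets pore depth rather than
diameter. Intercepts (6.8, −18.25, −100 nm) are solved so that
class-conditional mean diameters at mid-window voltage and 15 °C equal the
class means typical of literature data (≈23, 47 and 104 nm). The residual
SD defaults to 15 nm, the within-class spread left after the voltage
contribution is removed from typical class SDs. Interpore distance is
diameter/0.35 plus 5 nm of noise, matching the ~0.35 pore-to-interpore
ratio of self-ordered NAA.

**Plausibility clamp.** Diameters are kept strictly inside (5, 350) nm by
redrawing the noise rather than clipping, so the bounds carry no
probability atoms; a record whose *mean* sits near a bound therefore
produces a slightly biased draw, which is why the parameter-recovery and
Monte-Carlo tests use configurations whose means stay clear of the bounds.

**Missingness.** Temperature and time are independently blanked with
probability 0.118 each (missing completely at random), leaving an expected
99·(1−0.118)² ≈ 77 complete cases out of 99 — the attrition level typical
of literature compilations. Diameter and voltage are never blanked; they
are near-universally reported. The class mix is an explicit parameter
(uniform thirds by default) because the composition of real compilations
varies and is often only partly documented.

**What the generator does not emulate:** skewed empirical voltage
distributions, inter-laboratory measurement offsets (SEM vs TEM vs AFM),
correlated missingness with publication year (an MCAR blanking is used),
concentration and current-density effects, and nonlinearities such as
pore widening during very long anodization. Tests passing on synthetic
data therefore validate the machinery — estimators, encodings, leakage
control, kinetics arithmetic — not the accuracy of any surrogate on real
literature data.

## Preprocessing conventions

* **Canonicalization** maps spelling/formula variants onto H2SO4, H2C2O4,
  H3PO4; unknown acids are flagged, not dropped silently.
* **Case-wise deletion** (no imputation): records missing any required
  modelling field are removed. Imputing mechanistically coupled process
  parameters would manufacture precision.
* **Encoding.** Two modes are provided because the two common conventions
  conflict for a 3-level categorical: `onehot` (three 0/1 indicators plus
  three standardized continuous columns, 6 inputs — the default) and
  `compact` (integer-coded electrolyte standardized like the continuous
  inputs, 4 inputs, matching a literal 4-neuron input layer). Indicators
  are never standardized.
* **Standardization** uses the population SD (divisor n) and is fitted on
  training rows only, then applied to test rows and re-fitted inside every
  cross-validation fold. This leakage control is the package's own choice;
  it costs nothing and removes a common source of optimistic CV scores.
* **Stratified split**: per-electrolyte allocation of round(n_class ·
  test_fraction) records to the test set (default 22 %), seeded shuffle
  within class, singleton classes kept in training.

## The surrogates

**MLR.** Ordinary least squares via `stats::lm`. Under one-hot encoding
the design uses reference-cell coding (first indicator dropped, intercept
added) so the normal equations are full rank. `mlr_slopes()`
de-standardizes coefficients back to nm/V, nm/°C, nm/min.

**Network.** A 64-32-16 rectifier network with linear output, trained by
mini-batch Adam (lr 0.001, β₁ 0.9, β₂ 0.999, ε 1e-8, batch 32, ≤1000
epochs, L2 1e-4) with an unstratified 15 % validation split and early
stopping at 50 epochs' patience, restoring the best-validation weights.
Numerical choices the architecture itself does not fix, made here and
documented as such:

* the target is centred and scaled internally during optimization (and
  predictions de-scaled), so a fixed 0.001 learning rate converges within
  the epoch budget regardless of the nm-scale response;
* weights are He-normal initialized (SD √(2/fan_in)), biases zero, with a
  single seed governing initialization, the validation split and batch
  shuffling — training is bit-reproducible;
* the rectifier derivative at exactly 0 is taken as 0;
* the loss is mean squared error (consistent with RMSE reporting), and a
  validation improvement smaller than 1e-10 counts as no improvement.

**Evaluation.** R² = 1 − SS_res/SS_tot, RMSE, MAE. Cross-validation uses
seeded near-equal folds (sizes differ by ≤1), unstratified, with fold
scores aggregated as mean and *population* SD — the divisor-k convention,
which is the one consistent with published fold-score tables that this
aggregation was checked against. The CV seed is independent of the
network seed.

On small noisy datasets (n ≈ 77, σ ≈ 25 nm) the linear surrogate
cross-validates better than the network in essentially every generator
seed — the ~4000-weight network overfits at this sample size — while both
reach similar training R². This direction of findings is asserted as a
stochastic property test (≥7 of 10 seeds), not as a point reproduction.

## Feature importance

Two deliberately simple attribution rules, normalized to sum to 100 %:
mean absolute first-layer weight per input column for the network, and
absolute (standardized) coefficients for MLR. Indicator columns of the
electrolyte are **summed** into one "electrolyte_type" entry — summation
is the only aggregation that preserves the 100 % total. Both rules are
first-order proxies: they ignore deeper-layer interactions, and the
reports carry a caveat field saying so. Permutation or Shapley-based
importance is intentionally out of scope.

## Release kinetics

**Unit convention (the central repair).** The package works throughout in
percent units: K in % · h^(−1/2) with Q(t) = K√t, t50 = (50/K)²,
t90 = (90/K)². Release-constant tables quoted in fraction units
(k ≈ 0.68–1.4 h^(−1/2)) are internally consistent with their own t50/t90
columns only when multiplied by 10 into percent units — e.g. (50/8)² =
39.06 h and (90/14)² = 41.33 h reproduce the tabulated 39.1 and 41.3 h.
`RELEASE_REFERENCE` stores the percent-unit constants, and
`release_table()` reports k = K/10 alongside.

**Initial release rate.** Defined operationally as the cumulative percent
released in the first hour, Q(1 h) = K, which reproduces tabulated
initial-rate columns exactly. The instantaneous profile slope at t = 1 h,
dQ/dt = K/2, is reported as a separately labelled column because "half the
constant" is the other definition in circulation.

**Effective diffusivity.** D_eff = D_bulk · (1−λ)²(1 − 2.104λ + 2.09λ³ −
0.95λ⁵) with λ = r_molecule/r_pore; the polynomial is clipped below at 0,
warned about above λ = 0.4 (its classical validity limit) and an error at
λ ≥ 1. Defaults describe ibuprofen (r = 0.37 nm, MW 206 Da, D_bulk =
6×10⁻⁶ cm²/s) with C0 = 100 mg/mL, ε = 0.3, τ = 1.5.

**The release constant** is computed two ways, and the discrepancy between
them is a finding, not a bug:

* `mechanistic`: K = s·√(D_eff·C0·ε/τ) — the dimensionally sound
  square-root (Higuchi-type) form, with one calibration scale s fixed so
  the 75 nm reference configuration returns K = 9.5 under default
  parameters. A product form without the square root is dimensionally
  inconsistent with K in h^(−1/2), so it is not implemented. Because the
  Renkin correction for a 0.37 nm molecule is tiny at these pore sizes,
  this mode varies K by only ~4 % from 30 to 150 nm pores.
* `empirical`: K = K_ref·(d/d_ref)^p with the exponent p ≈ 0.446 fitted
  once by log-log OLS to the five reference (d, K) pairs, reproducing
  their much stronger (~2×) diameter dependence.

The reference table's diameter dependence therefore cannot come from
steric hindrance alone; mechanisms outside this model (e.g.
diameter-dependent loading or wetting) would be needed. Both modes are
exposed; neither is presented as "the" mechanism.

**Sensitivity.** t50 ∝ τ/(D·ε), so one-at-a-time ±δ perturbations change
t50 by exactly ±δ (tortuosity) and 1/(1±δ)−1 (diffusivity, porosity).
The perturbation magnitude δ is a required argument without a default:
published "±25 %" summaries do not state the δ they used, so the package
makes no claim of reproducing them.

**Geometry.** Hexagonal-array porosity ε = (π/2√3)(d_p/D_int)², the
standard closed form for cylindrical pores on a hexagonal lattice (bounded
by π/2√3 ≈ 0.9069 when pores touch); loading capacity assumes pores
completely filled with solution at C0 (no adsorbed-layer term):
loading = ε · depth · C0, converted to µg/cm².

## Degenerate inputs and tie-breaks

Zero-variance responses make R² undefined (returned as NA with a warning);
zero-variance training columns, rank-deficient designs, all-zero
importance scores, molecules larger than pores, and pore diameters at or
above the interpore distance are all errors with named causes. Report
tables round to one decimal; all internal computation is full precision.

## Problem sizes used in the tests

The suite validates stochastic properties at sizes chosen to keep the
whole run fast while leaving comfortable statistical margins: parameter
recovery with 100 replicates at n = 200 (±2 SE coverage ≥ 90 %),
MLR-vs-network cross-validation direction over 10 generator seeds at
n = 77, Monte-Carlo convergence checks at n = 10⁵, and full-pipeline
determinism at n = 99–100. The network's noise-free linear-fit check uses
n = 500.

## Known limitations

* The surrogates are fitted to synthetic data in all shipped examples;
  numbers quoted in the README describe those runs, not any literature
  dataset.
* The release model assumes constant diffusivity, uniform loading, ideal
  cylindrical pores, no drug–wall adsorption and no burst term; pore-size
  distributions and modulated-pore architectures are out of scope.
* Concentration and current density are carried through the schema but
  excluded from the models (inconsistent reporting in source literatures).
* Weight-based importance is first-order only, and the network's
  importance pattern depends on the encoding mode chosen.
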