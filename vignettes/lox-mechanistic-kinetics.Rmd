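---
title: "Mechanistic kinetics of L-lactate oxidase: model, synthetic data and fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic kinetics of L-lactate oxidase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loxkin)
```

## The kinetic scheme

*Aerococcus viridans* L-lactate oxidase (LOX) is an FMN-dependent
flavoenzyme that oxidizes L-lactate to pyruvate and reduces O2 to H2O2 by
a ping-pong mechanism of two half-reactions. `loxkin` encodes the
catalytic cycle as mass action over four enzyme species:

```
        k1[S]        k3           k5             k7[O2]
E_ox  <------>  E_ox.S  <---->  E_red.P  <---->  E_red  ------>  E_ox
        k2           k4           k6
```

* **Reductive half-reaction** — lactate binding (`k1`, `k2`), hydride
  transfer reducing the FMN (`k3`, reverse `k4`), and pyruvate release
  (`k5`, re-binding `k6`). The reduced enzyme-pyruvate species is a
  charge-transfer complex with a distinct absorbance band near 530 nm;
  the FMN oxidation state itself is read at 455 nm.
* **Oxidative half-reaction** — re-oxidation of the reduced flavin by O2
  (`k7`, second order), regenerating the resting enzyme.

The state vector also carries free lactate, pyruvate and O2, so full
turnover, single-turnover (anaerobic) and reoxidation experiments are all
the same ODE system with different initial conditions. The four enzyme
species are conserved exactly by construction; the integrator
(`deSolve::lsoda`, stiff-capable) is run at relative tolerance 1e-8 and
absolute tolerance 1e-12 M because nM-uM enzyme coexists with mM
substrate, and the test suite requires conservation drift below 1e-6 on
every trajectory.

### Defaults that are modelling choices, not measurements

* `k4 = 0`: the observed reduction rate extrapolates through the origin as
  a function of lactate concentration, so reverse FMN oxidation by bound
  pyruvate is not detectable. `k6 = 0`: product re-binding has never been
  quantified. Both remain settable fields for sensitivity analyses.
* `k1 = 1e8` M^-1 s^-1 with `k2 = Kd * k1`: binding is treated as rapid
  equilibrium near the diffusion limit. The observed fast-phase rate then
  saturates as `k_obs = k3 [S]/(K + [S])` with
  `K = (k2 + k3)/k1 = Kd + k3/k1`; with `k1 = 1e8` the bias `k3/k1` is
  below 0.5% of `Kd` for every parameter set studied, so the fitted
  dissociation constant can be compared directly with the generating one.
  A slower `k1` (e.g. 1e7) leaves all conclusions intact but makes the
  apparent `K` visibly larger than `Kd` (≈4% for the Y215F set).
* [O2] is clamped by default (pseudo-first-order), matching the analysis
  of reoxidation experiments where `k_obs` is linear in [O2]; a
  consumable-O2 mode exists for completeness.

## The turnover algebra

With the reductive flux irreversible (`k4 = k6 = 0`) the mean turnover
time at saturating lactate is the sum of the times spent in the three
surviving steps:

\[ \frac{1}{k_\mathrm{cat,app}} = \frac{1}{k_3} + \frac{1}{k_5} +
   \frac{1}{k_7[\mathrm{O_2}]} \]

`kcat_apparent()` evaluates this; `solve_k5_from_kcat()` inverts it for
`k5` — the route used when no separable slow phase or charge-transfer
band reports pyruvate release directly — and raises an explicit
infeasibility error when the stated `kcat` exceeds what `k3` and
`k7[O2]` allow. At O2 saturation `kcat_sat = k3 k5/(k3 + k5)`
(`kcat_saturating()`), and the Michaelis constant for oxygen follows as
`Km(O2) = kcat_sat/k7` (`km_oxygen()` — always from the derived
`kcat_sat`, never from the air-saturation value). The share of the
turnover time a step occupies, `(1/k_i) / \sum_j (1/k_j)`, is the
step's rate-limitation fraction (`rate_limitation_fractions()`); the
three fractions sum to 1 by construction.

These are algebraic identities, and the tests verify them both ways: the
apparent kcat is exactly hyperbolic in [O2] with the derived `kcat_sat`
and `Km(O2)`, and a long ODE turnover simulation at saturating lactate
reproduces `kcat_apparent()` to 1%.

```{r algebra}
kcat_apparent(k3 = 8.2, k5 = 26, k7 = 1.0e5, o2 = 250e-6)
solve_k5_from_kcat(kcat_app = 5.0, k3 = 8.2, k7 = 1.0e5, o2 = 250e-6)
1e6 * km_oxygen(kcat_saturating(270, 141), 1.8e6)   # uM
```

## What the synthetic-data generator emulates

`simulate_reduction_experiment()`, `simulate_reoxidation_experiment()`
and `simulate_initial_rate_table()` generate the three experiment types
at the study's own conditions:

* stopped-flow enzyme 5 uM (bound FMN), lactate 0.25-10 mM, O2 60-500 uM
  after mixing; initial-rate assays at 50 nM enzyme, 0.05-10 mM lactate,
  250 uM O2 (air saturation), triplicate with 3% CV multiplicative rate
  noise;
* an instrument model with 1.5 ms dead time (points before it are
  dropped, not extrapolated), 0.5 ms sampling, and additive homoscedastic
  Gaussian absorbance noise of 1 mAU — one seeded RNG stream per
  experiment, with the seed recorded in the trace metadata so fixtures
  are bit-reproducible;
* a Beer-Lambert optical model: 12500 M^-1 cm^-1 for protein-bound
  oxidized FMN at 455 nm. The reduced-species coefficients are free
  modelling choices (nothing is published for them): `E_red` transparent
  at 455 nm, the charge-transfer complex at 10% of the oxidized 455 nm
  absorbance — which makes the slow release phase carry roughly 10% of
  the total 455 nm amplitude, the regime in which a second phase is just
  analyzable — and 1500 M^-1 cm^-1 at 530 nm (zero for variants without
  an observable charge-transfer band).

Mixing is instantaneous at t = 0 with post-mix concentrations given
directly. Initial rates are measured exactly as an experiment would:
slope of pyruvate over a window consuming at most 5% of the substrate,
after a burn-in of 10 relaxation times of the enzyme cycle (the analytic
cycle steady state sizes the window; a design that cannot reach steady
state within the 5% budget raises a window-too-long error instead of
returning a biased rate).

What the generator does **not** emulate: diode-array spectral matrices
(single wavelengths only), temperature effects on the charge-transfer
band, syringe-dilution artifacts, photobleaching, or heteroscedastic
detector noise. Passing recovery tests on these synthetic data therefore
demonstrates correctness of the fitting machinery under the stated noise
model, not robustness to every pathology of real stopped-flow data.

## Fitting procedures and their numerical choices

**Exponential phase extraction** (`fit_exponentials()`): least squares on
log-parameterized rates (Levenberg-Marquardt), with starting values from
a noise-aware log-linear regression of the tail (slow phase) and of the
early residual after peeling (fast phase), plus two fallback starts that
split the single-exponential rate. A second phase is accepted only if
(i) its amplitude is at least 5% of the total, (ii) the rates are
separated at least 3-fold — the separation below which the two phases
cannot be determined independently — and (iii) both rates are determinate
(relative standard error < 25%); otherwise one phase is reported.
Criterion (iii) matters for near-merged traces (wild type at pH 6.5,
where `k5` is within 2-fold of `k3`): a two-exponential fit of such a
trace sits on a ridge and splits arbitrarily. When the slow rate is known
from better-separated traces it can be fixed (`fix_slow_rate`), leaving
the fast rate unbiased at low substrate where the phases merge — the
package's analogue of the protocol in which the slow phase is analyzed
only above the concentration where it separates. Flat traces are
detected by comparing a running-mean-smoothed range against the range
expected from pure noise and rejected with an explicit no-signal error.

**Concentration dependencies**: `fit_kobs_saturation()` fits
`k_obs = k_red [S]/(Kd + [S])`, optionally with a free intercept whose
indistinguishability from zero supports `k4 ≈ 0`; designs without
curvature raise identifiability warnings rather than returning a
meaningless `Kd`. `fit_kox_linear()` is a straight-line fit whose slope
is `k_ox`; with `relative_errors = TRUE` it weights by `1/[O2]^2`, which
calibrates the slope standard error when rates carry a constant
coefficient of variation (verified by Monte-Carlo coverage in the test
suite). `fit_michaelis_menten()` fits the initial-rate hyperbola with
Hanes-linearization starts.

**Combined kinetic simulation and fitting** (`fit_ct_trace_ode()`): the
530 nm charge-transfer trace is fitted by nonlinear least squares in
which each residual evaluation integrates the full scheme; `k3` and `k5`
are free (log scale), binding and optics fixed. Because the extinction
coefficient of the intermediate is fixed, the trace amplitude breaks the
classic slow/fast ambiguity of consecutive reactions; the fitter still
runs from two starts (given and swapped) and keeps the lower-residual
optimum. Standard errors come from the Jacobian-based covariance at the
optimum; no bootstrap by default.

**Uncertainty aggregation**: the slow phase is concentration-independent,
so it is averaged across traces where the phases are separable; `k_obs`
values enter the concentration-dependence fits unweighted (the noise
model is homoscedastic in absorbance, and the per-trace rate errors are
comparable within a series).

## The emergent Km for lactate

The cycle's steady-state rate is exactly hyperbolic in lactate with
`Km(S) = kcat_app (k2 + k3)/(k1 k3)`. This is *below* the binding `Kd`
whenever turnover is slower than reduction, and with the published
constants for Y215H (`Kd = 0.55` mM, `k3 = 8.2` /s,
`kcat_app ≈ 5.0` /s) it evaluates to ≈0.34 mM — not the 0.52 mM
reported from experiment. The package treats the printed `Km` values as
arithmetic inputs (e.g. for catalytic efficiencies), never as recovery
targets for the simulator, and the tests assert the mechanistic identity
instead.

## Design decisions that were genuinely open

* **Binding constants**: not reported anywhere; fixed at rapid
  equilibrium (`k1 = 1e8`, `k2 = Kd k1`) as above. The 530 nm ODE fit
  inherits this assumption, and reports note it.
* **Wild type at pH 6.5**: the published `k5 = 141` /s is treated as an
  input constant (it derives from earlier data), because with `k5`
  within 2-fold of `k3` neither the 455 nm phases nor a 20 °C
  charge-transfer band can separate it; the pipeline's wild-type
  transient estimates are accordingly blended, and the analysis scripts
  say so rather than pretending recovery.
* **Slow-phase aggregation rule**: mean over traces with fast/slow
  separation ≥ 3-fold relative to the provisional slow-rate median,
  fixed-slow refits elsewhere. The alternative (drop low concentrations
  entirely) gives the same answers but wastes the fast-phase information
  at those concentrations.
* **Rounding for display** follows the reporting convention of the field
  (2 significant figures for rates and folds, integer percentages); full
  precision is retained in all machine outputs.

## Problem sizes

The default in-silico study uses 6 lactate concentrations x 2 wavelengths
for reduction, 4 O2 concentrations for reoxidation, and an 8-concentration
triplicate rate table per variant; recovery properties are established
over 10 instrument seeds and standard-error calibration over 200
Monte-Carlo replicates. These sizes give sub-percent Monte-Carlo error on
the quantities asserted while keeping the whole suite fast on a single
CPU.

## Known limitations

* No global multi-wavelength or multi-trace simultaneous fitting; traces
  and concentration dependencies are fitted sequentially, as in the
  original analysis.
* No dead-time deconvolution beyond truncation; rates near or above
  1/dead-time (≈700 /s) are recovered with visibly inflated variance.
* No pH-titration model: constants are per-pH inputs.
* No closed-form two-substrate steady-state rate law; `Km(S)` is handled
  empirically by the Michaelis-Menten fitter.
* The 530 nm band amplitude is a free optical choice; absolute 530 nm
  amplitudes carry no information about the published system.
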