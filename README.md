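# loxkin — mechanistic kinetics of L-lactate oxidase half-reactions

`loxkin` models and fits the catalytic cycle of *Aerococcus viridans*
L-lactate oxidase (LOX), an FMN-dependent flavoenzyme that oxidizes
L-lactate to pyruvate and O2 to H2O2 by a ping-pong (two half-reaction)
mechanism. It is written for enzyme kineticists who work with
stopped-flow and steady-state data: it simulates the experiments,
implements the standard pre-steady-state and steady-state fitting
procedures, and carries the closed-form algebra that links microscopic
rate constants to observable turnover parameters — the layer in which
wild-type LOX and active-site variants such as Y215F and Y215H are
compared.

## The model

Mass action over four enzyme species (oxidized free enzyme, Michaelis
complex, reduced enzyme–pyruvate charge-transfer complex, reduced free
enzyme) plus free lactate, pyruvate and O2:

```
        k1[S]        k3           k5             k7[O2]
E_ox  <------>  E_ox.S  ---->  E_red.P  ---->  E_red  ------>  E_ox
        k2      (k4 = 0)       (k6 = 0)
```

With the reductive flux irreversible, the apparent turnover number at a
stated O2 concentration obeys the reciprocal-sum relation

    1/kcat_app = 1/k3 + 1/k5 + 1/(k7·[O2])

which can be inverted for the pyruvate-release constant `k5` when only
`kcat_app`, `k3` (= `k_red` from the fast 455 nm stopped-flow phase) and
`k7` (= `k_ox` from the k_obs–[O2] slope) are measurable. At O2
saturation `kcat = k3·k5/(k3+k5)` and `Km(O2) = kcat/k7`; the fraction of
turnover time spent in step *i* is `(1/k_i)/Σ(1/k_j)`.

Core surfaces:

| layer | functions |
|---|---|
| mechanism & algebra | `lox_rates()`, `simulate_lox()`, `kcat_apparent()`, `solve_k5_from_kcat()`, `kcat_saturating()`, `km_oxygen()`, `rate_limitation_fractions()`, `observed_decay_rates()` |
| synthetic experiments | `lox_optics()`, `lox_instrument()`, `simulate_reduction_experiment()`, `simulate_reoxidation_experiment()`, `simulate_initial_rate_table()`, `write_traces()`/`read_traces()` |
| transient fitting | `fit_exponentials()`, `fit_kobs_saturation()`, `fit_kox_linear()`, `fit_ct_trace_ode()`, `fit_transient_experiments()` |
| steady state & summary | `fit_michaelis_menten()`, `derive_variant_summary()`, `compare_variants()` |
| workflow | `read_experiment_config()`, `run_lox_pipeline()`, `lox_reference_constants()` |

## Worked example

Derive the Y215H variant's pyruvate-release constant and the Michaelis
constants for O2 from published-style constants:

```r
library(loxkin)

# Y215H at pH 6.5: kcat_app = 5.0 /s at 250 uM O2, k_red = 8.2 /s,
# k_ox = 1.0e5 /M/s  ->  k5 by inverting the reciprocal-sum relation
solve_k5_from_kcat(kcat_app = 5.0, k3 = 8.2, k7 = 1.0e5, o2 = 250e-6)
#> [1] 26.28205

# Km(O2) = k3*k5/(k3+k5)/k7, in uM, for wild type / Y215F / Y215H
1e6 * km_oxygen(kcat_saturating(270, 141), 1.8e6)
#> [1] 51.45985
1e6 * km_oxygen(kcat_saturating(120, 20), 7.0e5)
#> [1] 24.4898
1e6 * km_oxygen(kcat_saturating(8.2, 26), 1.0e5)
#> [1] 62.33918
```

So pyruvate release in Y215H runs at ~26 s⁻¹ (slower than wild type's
141 s⁻¹ but, unusually, *faster* than its own FMN reduction at 8.2 s⁻¹),
and the O2 Michaelis constants stay in the 24–62 µM range — all three
enzymes remain near-saturated in air-equilibrated buffer (250 µM O2).

Simulate a stopped-flow charge-transfer trace and refit it by combined
kinetic simulation and fitting:

```r
truth <- lox_rates(kd = 0.28e-3, k3 = 150, k5 = 17, k7 = 7e5)
tset  <- simulate_reduction_experiment(truth, lox_optics(),
                                       lox_instrument(noise_sd = 0),
                                       e0 = 4.3e-6, lactate_concs = 1e-2,
                                       t_end = 0.4)
tr530 <- Filter(function(tr) tr$wavelength == 530, tset)[[1]]
init  <- truth; init$k3 <- 60; init$k5 <- 45
fit_ct_trace_ode(tr530, init, lox_optics())
#> <lox_ct_fit> k3 = 150 +/- 6.3e-11 /s, k5 = 17 +/- 2.2e-12 /s (residual sd 4.31e-15 AU)
```

The full in-silico study (simulate → fit-transient → fit-steady →
derive → compare for all three enzymes) is a sequence of narrative
drivers:

```sh
Rscript analysis/01_simulate.R          # traces + rate tables -> results/analysis/
Rscript analysis/02_fit_transient.R     # k_red, Kd, k_slow, k_ox per variant
Rscript analysis/03_fit_steady_state.R  # kcat_app, Km(S)
Rscript analysis/04_derive_summary.R    # k5, kcat_sat, Km(O2), fold changes
```

or a single config-driven call,
`run_lox_pipeline(system.file("extdata/default_config.yaml", package = "loxkin"), out_dir)`,
which is deterministic given the config (all randomness is seeded) and
writes trace CSVs, fit JSONs, a variant summary table and a fold-change
report.

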