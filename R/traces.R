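#' Stopped-flow absorbance trace
#'
#' A time-stamped absorbance series at one wavelength with experiment
#' metadata (variant label, concentrations, enzyme concentration, seed).
#' Time starts at or after the instrument dead time and is strictly
#' increasing.
#'
#' @param time time points (s), strictly increasing
#' @param absorbance absorbance values (AU), same length as `time`
#' @param wavelength 455 or 530 (nm)
#' @param meta named list of metadata (variant, lactate_M or o2_M, e0_M, seed)
#' @return an object of class `lox_trace`
#' @export
lox_trace <- function(time, absorbance, wavelength, meta = list()) {
  if (length(time) != length(absorbance))
    stop_invalid_input("time and absorbance must have equal length")
  if (length(time) > 1 && any(diff(time) <= 0))
    stop_invalid_input("time must be strictly increasing")
  if (!wavelength %in% c(455, 530))
    stop_invalid_input("wavelength must be 455 or 530")
  structure(list(time = as.numeric(time), absorbance = as.numeric(absorbance),
                 wavelength = as.numeric(wavelength), meta = meta),
            class = "lox_trace")
}

#' @export
print.lox_trace <- function(x, ...) {
  cat(sprintf("<lox_trace> %d points at %g nm, t = [%.4g, %.4g] s\n",
              length(x$time), x$wavelength, min(x$time), max(x$time)))
  if (length(x$meta) > 0)
    cat("  ", paste(names(x$meta), unlist(x$meta), sep = "=",
                    collapse = "  "), "\n")
  invisible(x)
}

#' @export
print.lox_trace_set <- function(x, ...) {
  cat(sprintf("<lox_trace_set> %d traces\n", length(x)))
  for (tr in x)
    cat(sprintf("  %g nm, %d pts, %s\n", tr$wavelength, length(tr$time),
                paste(names(tr$meta), unlist(tr$meta), sep = "=",
                      collapse = " ")))
  invisible(x)
}

lox_trace_set <- function(traces) {
  structure(traces, class = "lox_trace_set")
}

# Sample an integrated trajectory through the instrument: truncate before
# dead time, sample at the fixed interval, add seeded Gaussian noise.
observe_trace <- function(rates, state0, optics, instrument, wavelength,
                          t_end, meta, o2_clamped = TRUE) {
  if (t_end <= instrument$dead_time)
    lox_stop("t_end must exceed the instrument dead time", "lox_invalid_window")
  t_obs <- seq(instrument$dead_time, t_end, by = instrument$sample_interval)
  sim <- simulate_lox(rates, state0, times = t_obs, o2_clamped = o2_clamped)
  sim <- sim[match(t_obs, sim$time), ]
  a <- absorbance_at(sim, optics, wavelength)
  if (instrument$noise_sd > 0)
    a <- a + stats::rnorm(length(a), sd = instrument$noise_sd)
  lox_trace(t_obs, a, wavelength, meta)
}

#' Simulate anaerobic reduction stopped-flow experiments
#'
#' Mixes all-oxidized enzyme with lactate under anaerobic conditions and
#' records 455 nm (FMN reduction) and 530 nm (charge-transfer complex)
#' traces for each lactate concentration, through the instrument model
#' (dead-time truncation, fixed sampling, additive noise). One seeded RNG
#' stream drives all noise in the experiment; the seed is recorded in every
#' trace's metadata.
#'
#' @param rates a [lox_rates()] object
#' @param optics a [lox_optics()] object
#' @param instrument a [lox_instrument()] object
#' @param e0 total enzyme (bound FMN) concentration (M), 1-50 uM
#' @param lactate_concs lactate concentrations after mixing (M)
#' @param t_end end of observation window (s)
#' @return a `lox_trace_set` with a 455 nm and a 530 nm trace per
#'   concentration
#' @export
simulate_reduction_experiment <- function(rates, optics, instrument,
                                          e0, lactate_concs, t_end) {
  check_positive(e0, "e0")
  if (e0 < 1e-6 || e0 > 5e-5)
    lox_warn("e0 outside the usual stopped-flow range 1-50 uM",
             "lox_design_warning")
  check_nonnegative(lactate_concs, "lactate_concs")
  if (any(lactate_concs <= 0))
    stop_invalid_input("lactate_concs must be > 0")
  set.seed(instrument$seed)
  traces <- list()
  for (s0 in lactate_concs) {
    state0 <- lox_state(E_ox = e0, S = s0, O2 = 0)
    for (wl in c(455, 530)) {
      meta <- list(experiment = "reduction",
                   variant = rates$label, lactate_M = s0, e0_M = e0,
                   seed = instrument$seed)
      traces[[length(traces) + 1L]] <-
        observe_trace(rates, state0, optics, instrument, wl, t_end, meta)
    }
  }
  lox_trace_set(traces)
}

#' Simulate reoxidation stopped-flow experiments
#'
#' Mixes fully reduced enzyme with oxygenated buffer and records the
#' single-phase 455 nm absorbance rise at each oxygen concentration. Oxygen
#' is clamped by default (pseudo-first-order conditions, under which the
#' noiseless trace is a single exponential with rate `k7 * o2`).
#'
#' @inheritParams simulate_reduction_experiment
#' @param o2_concs oxygen concentrations after mixing (M)
#' @param o2_clamped hold O2 constant (default) or consume it
#' @return a `lox_trace_set` of 455 nm traces
#' @export
simulate_reoxidation_experiment <- function(rates, optics, instrument,
                                            e0, o2_concs, t_end,
                                            o2_clamped = TRUE) {
  check_positive(e0, "e0")
  check_nonnegative(o2_concs, "o2_concs")
  set.seed(instrument$seed)
  traces <- list()
  for (o2 in o2_concs) {
    state0 <- lox_state(E_red = e0, O2 = o2)
    meta <- list(experiment = "reoxidation",
                 variant = rates$label, o2_M = o2, e0_M = e0,
                 seed = instrument$seed)
    traces[[length(traces) + 1L]] <-
      observe_trace(rates, state0, optics, instrument, 455, t_end, meta,
                    o2_clamped = o2_clamped)
  }
  lox_trace_set(traces)
}

#' Simulate a steady-state initial-rate table
#'
#' For each lactate concentration, integrates a full turnover (oxygen
#' clamped, as for an air-equilibrated open cuvette) and measures the
#' initial rate as the slope of pyruvate over an early window consuming at
#' most 5% of the substrate, after a burn-in long enough for the enzyme
#' cycle to relax to its steady state. Rates are returned as `v/e0`
#' (s^-1, per bound FMN) with multiplicative Gaussian noise of coefficient
#' of variation `noise_cv` per replicate.
#'
#' @param rates a [lox_rates()] object
#' @param e0 enzyme concentration (M); assay-scale (default 50 nM), well
#'   below stopped-flow concentrations so that many turnovers fit into the
#'   5% consumption budget
#' @param lactate_concs lactate concentrations (M), spanning below and
#'   above the Michaelis constant
#' @param o2 fixed oxygen concentration (M), default air saturation 250 uM
#' @param replicates technical replicates per concentration
#' @param noise_cv coefficient of variation of the multiplicative rate noise
#' @param seed RNG seed
#' @return data.frame with columns `lactate_M`, `replicate`,
#'   `v_over_e0_per_s`
#' @export
simulate_initial_rate_table <- function(rates, e0 = 5e-8, lactate_concs,
                                        o2 = 250e-6, replicates = 3,
                                        noise_cv = 0.03, seed = 1L) {
  check_positive(e0, "e0"); check_positive(o2, "o2")
  check_nonnegative(noise_cv, "noise_cv")
  if (replicates < 1) stop_invalid_input("replicates must be >= 1")
  set.seed(as.integer(seed))
  rows <- lapply(lactate_concs, function(s0) {
    v0 <- initial_rate_from_ode(rates, e0, s0, o2)
    noise <- if (noise_cv > 0) stats::rnorm(replicates, 1, noise_cv) else
      rep(1, replicates)
    data.frame(lactate_M = s0, replicate = seq_len(replicates),
               v_over_e0_per_s = (v0 / e0) * noise)
  })
  do.call(rbind, rows)
}

# Noiseless initial rate (M/s) from an ODE turnover simulation. The
# analytic cycle steady state sizes the window: burn-in of 10 relaxation
# times of the reductive chain, then a measurement span short enough to
# keep total substrate consumption under 5%.
initial_rate_from_ode <- function(rates, e0, s0, o2) {
  v_ss <- cycle_steady_state_rate(rates, s0, o2) * e0    # M/s estimate
  lam <- observed_decay_rates(rates, s0)
  relax <- lam[lam > 1e-9]
  t_relax <- 1 / min(c(relax, rates$k7 * o2))
  t_burn <- 10 * t_relax
  budget <- 0.05 * s0 / v_ss                              # time to 5% consumed
  if (t_burn > 0.5 * budget)
    lox_stop(paste0("measurement window too long: the enzyme cycle cannot ",
                    "reach steady state before 5% of the substrate is ",
                    "consumed; lower e0 or raise the lactate concentration"),
             "lox_window_too_long")
  t_end <- min(t_burn + 20 * t_relax, 0.8 * budget)
  times <- seq(0, t_end, length.out = 60)
  sim <- simulate_lox(rates, lox_state(E_ox = e0, S = s0, O2 = o2), times)
  keep <- sim$time >= t_burn
  fit <- stats::lm(P ~ time, data = sim[keep, ])
  unname(stats::coef(fit)["time"])
}
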