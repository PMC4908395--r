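#' Species state of the lactate oxidase scheme
#'
#' A named concentration vector (molar) over the four enzyme species of the
#' catalytic cycle — oxidized free enzyme `E_ox`, Michaelis complex
#' `E_ox_S`, reduced enzyme-pyruvate (charge-transfer) complex `E_red_P`,
#' reduced free enzyme `E_red` — plus free lactate `S`, pyruvate `P` and
#' oxygen `O2`. The four enzyme species are conserved along any trajectory.
#'
#' @param E_ox,E_ox_S,E_red_P,E_red enzyme species concentrations (M)
#' @param S,P,O2 lactate, pyruvate, oxygen concentrations (M)
#' @return a named numeric vector of class `lox_state`
#' @export
lox_state <- function(E_ox = 0, E_ox_S = 0, E_red_P = 0, E_red = 0,
                      S = 0, P = 0, O2 = 0) {
  x <- c(E_ox = E_ox, E_ox_S = E_ox_S, E_red_P = E_red_P, E_red = E_red,
         S = S, P = P, O2 = O2)
  check_nonnegative(x, "concentrations")
  structure(x, class = c("lox_state", "numeric"))
}

lox_species <- c("E_ox", "E_ox_S", "E_red_P", "E_red", "S", "P", "O2")
enzyme_species <- c("E_ox", "E_ox_S", "E_red_P", "E_red")

#' Mass-action time derivatives of the lactate oxidase scheme
#'
#' The reductive half-reaction is binding (`k1`/`k2`), FMN reduction
#' (`k3`/`k4`) and pyruvate release (`k5`/`k6`); the oxidative half-reaction
#' is re-oxidation of reduced FMN by O2 (`k7`). With `o2_clamped = TRUE`
#' (the default, matching pseudo-first-order stopped-flow conditions) the O2
#' pool is held constant; otherwise one O2 is consumed per `k7` event.
#'
#' @param state a [lox_state()] (or named numeric vector over the same species)
#' @param rates a [lox_rates()] object
#' @param o2_clamped hold `O2` constant (pseudo-first-order) or consume it
#' @return named numeric vector of time derivatives (M/s)
#' @export
lox_derivatives <- function(state, rates, o2_clamped = TRUE) {
  state <- state[lox_species]
  if (any(is.na(state))) stop_invalid_input("state is missing species")
  check_nonnegative(unclass(state), "state")
  v1 <- rates$k1 * state[["E_ox"]] * state[["S"]]
  v2 <- rates$k2 * state[["E_ox_S"]]
  v3 <- rates$k3 * state[["E_ox_S"]]
  v4 <- rates$k4 * state[["E_red_P"]]
  v5 <- rates$k5 * state[["E_red_P"]]
  v6 <- rates$k6 * state[["E_red"]] * state[["P"]]
  v7 <- rates$k7 * state[["E_red"]] * state[["O2"]]
  c(E_ox    = -v1 + v2 + v7,
    E_ox_S  =  v1 - v2 - v3 + v4,
    E_red_P =  v3 - v4 - v5 + v6,
    E_red   =  v5 - v6 - v7,
    S       = -v1 + v2,
    P       =  v5 - v6,
    O2      = if (o2_clamped) 0 else -v7)
}

# deSolve-facing RHS; no validation in the inner loop. Small negative
# excursions within integrator tolerance are left to the solver.
lox_rhs_desolve <- function(t, y, parms) {
  v1 <- parms$k1 * y[1L] * y[5L]
  v2 <- parms$k2 * y[2L]
  v3 <- parms$k3 * y[2L]
  v4 <- parms$k4 * y[3L]
  v5 <- parms$k5 * y[3L]
  v6 <- parms$k6 * y[4L] * y[6L]
  v7 <- parms$k7 * y[4L] * y[7L]
  list(c(-v1 + v2 + v7,
         v1 - v2 - v3 + v4,
         v3 - v4 - v5 + v6,
         v5 - v6 - v7,
         -v1 + v2,
         v5 - v6,
         if (parms$o2_clamped) 0 else -v7))
}

#' Integrate the lactate oxidase scheme
#'
#' Stiff-capable integration (deSolve's `lsoda`) of the full mass-action
#' scheme at tight tolerances (relative 1e-8, absolute 1e-12 M), chosen
#' because enzyme species at nM-uM coexist with mM substrate.
#'
#' @param rates a [lox_rates()] object
#' @param state0 initial [lox_state()]
#' @param times output time grid (s); must start at 0
#' @param o2_clamped hold O2 constant (default) or consume it
#' @param rtol,atol integrator tolerances
#' @return a data.frame with columns `time` and the seven species (M)
#' @export
simulate_lox <- function(rates, state0, times, o2_clamped = TRUE,
                         rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(rates, "lox_rates"))
  if (times[1] != 0) times <- c(0, times)
  y0 <- as.numeric(state0[lox_species])
  parms <- c(rates[rate_fields], list(o2_clamped = o2_clamped))
  out <- deSolve::lsoda(y = y0, times = times, func = lox_rhs_desolve,
                        parms = parms, rtol = rtol, atol = atol,
                        maxsteps = 5e4)
  out <- as.data.frame(out)
  names(out) <- c("time", lox_species)
  out
}

#' Apparent turnover number at a stated oxygen concentration
#'
#' The turnover time at saturating lactate is the sum of the mean times
#' spent in FMN reduction, pyruvate release, and re-oxidation:
#' `1/kcat_app = 1/k3 + 1/k5 + 1/(k7 * o2)`.
#'
#' @param k3 FMN reduction rate constant (s^-1)
#' @param k5 pyruvate release rate constant (s^-1)
#' @param k7 FMN re-oxidation rate constant (M^-1 s^-1)
#' @param o2 oxygen concentration (M)
#' @return apparent kcat (s^-1)
#' @export
kcat_apparent <- function(k3, k5, k7, o2) {
  check_positive(k3, "k3"); check_positive(k5, "k5")
  check_positive(k7, "k7"); check_positive(o2, "o2")
  1 / (1 / k3 + 1 / k5 + 1 / (k7 * o2))
}

#' Solve for the pyruvate release rate constant from an apparent kcat
#'
#' Inverts the reciprocal-sum relation for `k5`:
#' `k5 = kcat_app / (1 - kcat_app/k3 - kcat_app/(k7*o2))`. Signals an
#' infeasibility error (class `lox_infeasible`) when the stated `kcat_app`
#' exceeds what `k3` and `k7*o2` allow.
#'
#' @param kcat_app apparent turnover number at `o2` (s^-1)
#' @inheritParams kcat_apparent
#' @return k5 (s^-1)
#' @export
solve_k5_from_kcat <- function(kcat_app, k3, k7, o2) {
  check_positive(kcat_app, "kcat_app")
  check_positive(k3, "k3"); check_positive(k7, "k7"); check_positive(o2, "o2")
  denom <- 1 - kcat_app / k3 - kcat_app / (k7 * o2)
  if (denom <= 0)
    lox_stop(sprintf(paste0(
      "kcat_app = %.3g s^-1 is infeasible: k3 = %.3g s^-1 and k7*[O2] = ",
      "%.3g s^-1 alone cap kcat below the stated value (denominator %.3g)"),
      kcat_app, k3, k7 * o2, denom), "lox_infeasible")
  kcat_app / denom
}

#' Turnover number at oxygen saturation and the Michaelis constant for O2
#'
#' At saturating O2 the re-oxidation term vanishes and
#' `kcat_sat = k3*k5/(k3+k5)`; the Michaelis constant for oxygen follows as
#' `km_O2 = kcat_sat/k7`.
#'
#' @inheritParams kcat_apparent
#' @return `kcat_saturating()`: kcat at O2 saturation (s^-1);
#'   `km_oxygen()`: K_m for O2 (M)
#' @export
kcat_saturating <- function(k3, k5) {
  check_positive(k3, "k3"); check_positive(k5, "k5")
  k3 * k5 / (k3 + k5)
}

#' @param kcat_sat turnover number at O2 saturation (s^-1)
#' @rdname kcat_saturating
#' @export
km_oxygen <- function(kcat_sat, k7) {
  check_positive(kcat_sat, "kcat_sat"); check_positive(k7, "k7")
  kcat_sat / k7
}

#' Per-step rate-limitation fractions of the apparent turnover
#'
#' The share of the turnover time spent in each step: the reciprocal of a
#' step's pseudo-first-order rate divided by the sum of reciprocals over
#' FMN reduction (`k3`), pyruvate release (`k5`) and re-oxidation
#' (`k7*o2`). The three fractions sum to 1.
#'
#' @inheritParams kcat_apparent
#' @return named numeric vector `c(k3 = , k5 = , k7_o2 = )`, each in `[0, 1]`
#' @export
rate_limitation_fractions <- function(k3, k5, k7, o2) {
  check_positive(k3, "k3"); check_positive(k5, "k5")
  check_positive(k7, "k7"); check_positive(o2, "o2")
  inv <- c(k3 = 1 / k3, k5 = 1 / k5, k7_o2 = 1 / (k7 * o2))
  inv / sum(inv)
}

#' Hyperbolic saturation value of the observed reduction rate
#'
#' The observed fast-phase rate at lactate concentration `s` under
#' rapid-equilibrium binding: `k_obs = k_red * s / (kd + s)`. Passes through
#' the origin, consistent with an undetectable reverse FMN oxidation by
#' bound pyruvate.
#'
#' @param s lactate concentration (M), `>= 0`
#' @param k_red limiting reduction rate at saturating lactate (s^-1)
#' @param kd apparent lactate dissociation constant (M)
#' @return k_obs (s^-1)
#' @export
kobs_saturation_value <- function(s, k_red, kd) {
  check_nonnegative(s, "s")
  check_positive(k_red, "k_red"); check_positive(kd, "kd")
  k_red * s / (kd + s)
}

#' Analytic decay rates of the reductive half-reaction
#'
#' Eigen-decay rates of the linear (pseudo-first-order) chain
#' `E_ox -> E_ox_S -> E_red_P -> E_red` with lactate held constant at `s`
#' and no oxygen. These are the rates an exponential fit of a noiseless
#' anaerobic reduction trace can recover; used as the independent oracle
#' for exponential-fit validation.
#'
#' @param rates a [lox_rates()] object
#' @param s fixed lactate concentration (M)
#' @param p fixed pyruvate concentration (M), default 0
#' @return non-negative decay rates (s^-1), sorted decreasing; the smallest
#'   is 0 (the reduced enzyme is absorbing)
#' @export
observed_decay_rates <- function(rates, s, p = 0) {
  stopifnot(inherits(rates, "lox_rates"))
  check_nonnegative(s, "s"); check_nonnegative(p, "p")
  a12 <- rates$k1 * s
  m <- matrix(c(
    -a12,            rates$k2,                    0,                0,
     a12, -(rates$k2 + rates$k3),          rates$k4,                0,
       0,              rates$k3, -(rates$k4 + rates$k5),  rates$k6 * p,
       0,                     0,           rates$k5,     -rates$k6 * p),
    nrow = 4, byrow = TRUE)
  ev <- eigen(m, only.values = TRUE)$values
  lam <- -Re(ev)
  lam[abs(lam) < 1e-10 * max(abs(lam), 1)] <- 0
  sort(lam, decreasing = TRUE)
}

#' Exact steady-state turnover rate of the catalytic cycle
#'
#' Solves the cyclic steady state of the four enzyme species with lactate
#' and oxygen held constant, returning `v/e0` (s^-1). Used internally to
#' size initial-rate measurement windows; also a closed-form cross-check
#' for ODE turnover simulations.
#'
#' @inheritParams observed_decay_rates
#' @param o2 fixed oxygen concentration (M)
#' @return v/e0 (s^-1)
#' @export
cycle_steady_state_rate <- function(rates, s, o2, p = 0) {
  stopifnot(inherits(rates, "lox_rates"))
  check_positive(s, "s"); check_positive(o2, "o2")
  # steady state of the 4-species cycle: M x = 0 with sum(x) = 1
  m <- matrix(c(
    -rates$k1 * s,               rates$k2,                  0,  rates$k7 * o2,
     rates$k1 * s, -(rates$k2 + rates$k3),          rates$k4,              0,
                0,              rates$k3, -(rates$k4 + rates$k5), rates$k6 * p,
                1,                     1,                  1,              1),
    nrow = 4, byrow = TRUE)
  x <- solve(m, c(0, 0, 0, 1))
  rates$k5 * x[3] - rates$k6 * p * x[4]
}
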