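#' Exponential phase extraction from a stopped-flow trace
#'
#' Fits `A(t) = baseline + sum_i a_i * exp(-r_i * (t - t0))` with one or two
#' phases by damped least squares (Levenberg-Marquardt on log rates, which
#' keeps rates positive). Starting values come from the log-linearized tail
#' (slow phase) and the early residual (fast phase).
#'
#' When `max_phases = 2` the model order is chosen by the phase-detection
#' rule: a second phase is accepted only if its amplitude is at least
#' `amp_frac_min` of the total amplitude **and** the two rates are separated
#' by at least `separation_min`-fold — the separation below which two phases
#' cannot be determined independently. Otherwise one phase is reported.
#'
#' With `fix_slow_rate` the slow rate is held at a known value (its
#' concentration-independent average from better-separated traces) and only
#' the fast rate and the amplitudes are fitted — the standard recourse when
#' the two phases are too close to determine independently.
#'
#' @param trace a [lox_trace()]
#' @param max_phases 1 or 2
#' @param amp_frac_min minimum amplitude share for accepting a second phase
#' @param separation_min minimum fast/slow rate ratio for a second phase
#' @param fix_slow_rate optional known slow-phase rate (s^-1); forces a
#'   two-phase model with that rate fixed
#' @return an object of class `lox_exp_fit`: `n_phases`, `phases` (a
#'   data.frame with `amplitude`, `rate`, `rate_se`, fast phase first),
#'   `baseline`, `residual_sd`, `t0`
#' @export
fit_exponentials <- function(trace, max_phases = 2, amp_frac_min = 0.05,
                             separation_min = 3, fix_slow_rate = NULL) {
  stopifnot(inherits(trace, "lox_trace"))
  if (!max_phases %in% c(1, 2)) stop_invalid_input("max_phases must be 1 or 2")
  t0 <- trace$time[1]
  tp <- trace$time - t0
  y <- trace$absorbance
  if (length(y) < 20)
    stop_invalid_input("need at least 20 points after the dead time")
  if (trace_is_flat(y))
    lox_stop("trace is flat: no kinetic signal to fit", "lox_no_signal")

  if (!is.null(fix_slow_rate)) {
    check_positive(fix_slow_rate, "fix_slow_rate")
    fitf <- try(fit_fixed_slow(tp, y, fix_slow_rate), silent = TRUE)
    if (inherits(fitf, "try-error"))
      lox_stop(paste0("fixed-slow-rate fit failed to converge: ",
                      attr(fitf, "condition")$message), "lox_fit_failure")
    return(exp_fit_result(fitf, t0))
  }

  fit1 <- try(fit_n_exp(tp, y, 1), silent = TRUE)
  if (max_phases == 1) {
    if (inherits(fit1, "try-error"))
      lox_stop(paste0("single-exponential fit failed to converge: ",
                      attr(fit1, "condition")$message), "lox_fit_failure")
    return(exp_fit_result(fit1, t0))
  }
  fit2 <- try(fit_n_exp(tp, y, 2), silent = TRUE)
  use2 <- FALSE
  if (!inherits(fit2, "try-error")) {
    amps <- abs(fit2$amplitude)
    ratio <- max(fit2$rate) / min(fit2$rate)
    # both rates must also be determinate (small relative standard error):
    # near-merged phases sit on a ridge and split arbitrarily
    determinate <- all(is.finite(fit2$rate_se)) &&
      all(fit2$rate_se < 0.25 * fit2$rate)
    use2 <- min(amps) / sum(amps) >= amp_frac_min &&
      ratio >= separation_min && determinate
  }
  if (use2) return(exp_fit_result(fit2, t0))
  if (inherits(fit1, "try-error"))
    lox_stop(paste0("exponential fit failed to converge: ",
                    attr(fit1, "condition")$message), "lox_fit_failure")
  exp_fit_result(fit1, t0)
}

exp_fit_result <- function(fit, t0) {
  ord <- order(fit$rate, decreasing = TRUE)   # fast phase first
  structure(list(n_phases = length(fit$rate),
                 phases = data.frame(amplitude = fit$amplitude[ord],
                                     rate = fit$rate[ord],
                                     rate_se = fit$rate_se[ord]),
                 baseline = fit$baseline, residual_sd = fit$residual_sd,
                 t0 = t0),
            class = "lox_exp_fit")
}

#' @export
print.lox_exp_fit <- function(x, ...) {
  cat(sprintf("<lox_exp_fit> %d phase(s), baseline %.4g AU, residual sd %.3g AU\n",
              x$n_phases, x$baseline, x$residual_sd))
  for (i in seq_len(x$n_phases))
    cat(sprintf("  phase %d: rate %.4g +/- %.2g /s, amplitude %.4g AU\n",
                i, x$phases$rate[i], x$phases$rate_se[i],
                x$phases$amplitude[i]))
  invisible(x)
}

# Core 1- or 2-exponential LM fit on log-rate parameterization. For the
# two-phase model, several starts are tried (tail-peeling guess plus
# splits of the single-exponential rate) and the best optimum kept.
fit_n_exp <- function(tp, y, n) {
  g <- exp_guess(tp, y, n)
  df <- data.frame(tp = tp, y = y)
  run_lm <- function(form, start) {
    minpack.lm::nlsLM(form, data = df, start = start,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  }
  if (n == 1) {
    fit <- run_lm(y ~ c0 + a1 * exp(-exp(lr1) * tp),
                  list(c0 = g$c0, a1 = g$a[1], lr1 = log(g$r[1])))
  } else {
    form <- y ~ c0 + a1 * exp(-exp(lr1) * tp) + a2 * exp(-exp(lr2) * tp)
    g1 <- exp_guess(tp, y, 1)
    starts <- list(
      list(c0 = g$c0, a1 = g$a[1], lr1 = log(g$r[1]),
           a2 = g$a[2], lr2 = log(g$r[2])),
      list(c0 = g1$c0, a1 = 0.9 * g1$a[1], lr1 = log(2 * g1$r[1]),
           a2 = 0.1 * g1$a[1], lr2 = log(g1$r[1] / 4)),
      list(c0 = g1$c0, a1 = 0.7 * g1$a[1], lr1 = log(5 * g1$r[1]),
           a2 = 0.3 * g1$a[1], lr2 = log(g1$r[1])))
    fit <- NULL
    for (st in starts) {
      cand <- try(run_lm(form, st), silent = TRUE)
      if (inherits(cand, "try-error")) next
      if (is.null(fit) || stats::deviance(cand) < stats::deviance(fit))
        fit <- cand
    }
    if (is.null(fit)) stop("two-exponential fit did not converge")
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    stats::setNames(rep(NA_real_, length(cf)), names(cf)))
  lr_idx <- grep("^lr", names(cf))
  a_idx <- grep("^a", names(cf))
  rate <- exp(unname(cf[lr_idx]))
  rate_se <- rate * unname(se[lr_idx])        # delta method on log rate
  list(amplitude = unname(cf[a_idx]), rate = rate, rate_se = rate_se,
       baseline = unname(cf["c0"]),
       residual_sd = stats::sd(stats::resid(fit)))
}

# Two-phase fit with the slow rate held fixed; only the fast rate and the
# amplitudes are free.
fit_fixed_slow <- function(tp, y, r_slow) {
  g <- exp_guess(tp, y, 2)
  df <- data.frame(tp = tp, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ c0 + a1 * exp(-exp(lr1) * tp) + a2 * exp(-r_slow * tp), data = df,
    start = list(c0 = g$c0, a1 = g$a[1], lr1 = log(max(g$r[1], 3 * r_slow)),
                 a2 = g$a[2]),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    stats::setNames(rep(NA_real_, length(cf)), names(cf)))
  r_fast <- exp(unname(cf["lr1"]))
  list(amplitude = unname(c(cf["a1"], cf["a2"])),
       rate = c(r_fast, r_slow),
       rate_se = c(r_fast * unname(se["lr1"]), 0),
       baseline = unname(cf["c0"]),
       residual_sd = stats::sd(stats::resid(fit)))
}

# Starting values: baseline from the tail, slow rate from a log-linear
# regression over a noise-aware window of intermediate decay, fast rate
# from the early residual after peeling the slow component. Log
# regressions only use points safely above the noise floor.
exp_guess <- function(tp, y, n) {
  m <- length(y)
  c0 <- mean(y[max(1, m - max(3, m %/% 10)):m])
  z <- y - c0
  sgn <- sign(sum(z[seq_len(max(3, m %/% 10))]))
  if (sgn == 0) sgn <- 1
  z <- z * sgn                                 # positive decay
  zmax <- max(z)
  noise <- stats::sd(diff(y)) / sqrt(2)
  floor_z <- max(3 * noise, zmax * 1e-6)
  if (n == 1) {
    use <- z > max(floor_z, 0.05 * zmax)
    if (sum(use) < 3) use <- z > zmax * 0.05
    r1 <- max(1 / max(tp[2:m]),
              -stats::coef(stats::lm(log(z[use]) ~ tp[use]))[2])
    return(list(c0 = c0, a = sgn * zmax, r = unname(r1)))
  }
  # slow phase: the stretch where the fast component is mostly gone but
  # the signal is still above noise
  slow_i <- which(z < 0.25 * zmax & z > floor_z)
  if (length(slow_i) < 5) slow_i <- which(z < 0.5 * zmax & z > floor_z)
  if (length(slow_i) >= 5) {
    slow <- stats::lm(log(z[slow_i]) ~ tp[slow_i])
    r_slow <- max(1 / max(tp), -stats::coef(slow)[2])
    a_slow <- exp(stats::coef(slow)[1])
  } else {
    r_slow <- 2 / max(tp)
    a_slow <- 0.1 * zmax
  }
  resid_early <- z - a_slow * exp(-r_slow * tp)
  head_i <- which(tp <= stats::quantile(tp, 0.25) &
                    resid_early > max(floor_z, 0.02 * zmax))
  if (length(head_i) >= 3) {
    fast <- stats::lm(log(resid_early[head_i]) ~ tp[head_i])
    r_fast <- max(3 * r_slow, -stats::coef(fast)[2])
    a_fast <- exp(stats::coef(fast)[1])
  } else {
    r_fast <- 10 * r_slow
    a_fast <- max(zmax - a_slow, 0.1 * a_slow)
  }
  list(c0 = c0, a = sgn * c(a_fast, a_slow),
       r = unname(c(r_fast, r_slow)))
}
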