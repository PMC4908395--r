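# Classed conditions so callers can distinguish bad input from infeasible
# parameter algebra or fit failure.

lox_stop <- function(msg, class, call. = FALSE, data = NULL) {
  cond <- errorCondition(msg, class = c(class, "lox_error"), data = data)
  stop(cond)
}

lox_warn <- function(msg, class, data = NULL) {
  cond <- warningCondition(msg, class = c(class, "lox_warning"), data = data)
  warning(cond)
}

stop_invalid_input <- function(msg) lox_stop(msg, "lox_invalid_input")

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_invalid_input(sprintf("`%s` must be a single finite value > 0 (got %s)",
                               name, paste(format(x), collapse = ", ")))
  invisible(x)
}

# TRUE when a trace carries no kinetic signal: the range of a
# noise-suppressing running mean is compared with the range expected from
# pure noise at the same length.
trace_is_flat <- function(y) {
  n <- length(y)
  noise_est <- stats::sd(diff(y)) / sqrt(2)
  w <- max(1L, min(25L, n %/% 4L))
  sm <- stats::filter(y, rep(1 / w, w), sides = 2)
  sm <- sm[!is.na(sm)]
  thresh <- max(4 * (noise_est / sqrt(w)) * sqrt(2 * log(max(n / w, 2))),
                1e-12)
  diff(range(sm)) < thresh
}

# Levenberg-Marquardt least squares via nls.lm with Jacobian-based
# covariance at the optimum. Robust to exactly-zero residuals (noiseless
# synthetic data), where the nls-object route can fail.
lm_least_squares <- function(resid_fn, start, maxiter = 200) {
  out <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxiter, ftol = 1e-14, ptol = 1e-14))
  n <- length(resid_fn(out$par))
  dof <- max(n - length(start), 1L)
  sigma2 <- out$deviance / dof
  se <- tryCatch(sqrt(diag(sigma2 * solve(out$hessian))),
                 error = function(e)
                   stats::setNames(rep(NA_real_, length(start)),
                                   names(start)))
  list(par = out$par, se = stats::setNames(se, names(start)),
       residual_sd = sqrt(sigma2), deviance = out$deviance,
       niter = out$niter)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop_invalid_input(sprintf("`%s` must be finite and >= 0", name))
  invisible(x)
}
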