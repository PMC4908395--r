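#' Hyperbolic fit of observed reduction rates against lactate concentration
#'
#' Fits `k_obs = k_red * s / (kd + s)` (optionally plus a free intercept)
#' by Levenberg-Marquardt least squares, yielding the limiting reduction
#' rate `k_red` and the apparent dissociation constant `kd`. With
#' `fix_origin = FALSE` the fit reports whether the free intercept is
#' statistically indistinguishable from zero, which supports a negligible
#' reverse FMN oxidation by bound pyruvate.
#'
#' An identifiability warning (class `lox_identifiability_warning`) is
#' issued when the design cannot constrain `kd`: fewer than 4 distinct
#' concentrations, or no curvature (all concentrations well below the
#' fitted `kd`). In that case `kd_reliable` is `FALSE`.
#'
#' @param points data.frame with columns `s` (lactate, M) and `kobs` (s^-1)
#' @param fix_origin force the curve through the origin (default `TRUE`)
#' @return an object of class `lox_sat_fit`: `k_red`, `kd`, `intercept`,
#'   standard errors, `intercept_zero` (logical or NA), `kd_reliable`
#' @export
fit_kobs_saturation <- function(points, fix_origin = TRUE) {
  stopifnot(is.data.frame(points), all(c("s", "kobs") %in% names(points)))
  check_nonnegative(points$s, "s")
  n_distinct <- length(unique(points$s))
  degenerate <- n_distinct < 2
  if (n_distinct < 4)
    lox_warn(sprintf(paste0("only %d distinct concentration(s): kd is not ",
                            "identifiable from this design"), n_distinct),
             "lox_identifiability_warning")
  if (degenerate) {
    return(structure(list(k_red = NA_real_, kd = NA_real_,
                          intercept = if (fix_origin) 0 else NA_real_,
                          k_red_se = NA_real_, kd_se = NA_real_,
                          intercept_se = NA_real_, intercept_zero = NA,
                          kd_reliable = FALSE),
                     class = "lox_sat_fit"))
  }
  kd0 <- stats::median(points$s)
  kr0 <- max(points$kobs) * (kd0 + max(points$s)) / max(points$s)
  s <- points$s; kobs <- points$kobs
  if (fix_origin) {
    fit <- lm_least_squares(function(p) kobs - p[["kr"]] * s / (p[["kd"]] + s),
                            c(kr = kr0, kd = kd0))
  } else {
    fit <- lm_least_squares(
      function(p) kobs - (p[["c0"]] + p[["kr"]] * s / (p[["kd"]] + s)),
      c(c0 = 0, kr = kr0, kd = kd0))
  }
  cf <- fit$par
  se <- fit$se
  kd_reliable <- max(points$s) >= 1.0 * cf[["kd"]] && n_distinct >= 4
  if (!kd_reliable && n_distinct >= 4)
    lox_warn("no curvature in the design (all concentrations below kd): kd unreliable",
             "lox_identifiability_warning")
  intercept <- if (fix_origin) 0 else unname(cf["c0"])
  intercept_se <- if (fix_origin) 0 else unname(se["c0"])
  structure(list(
    k_red = unname(cf["kr"]), kd = unname(cf["kd"]),
    intercept = intercept,
    k_red_se = unname(se["kr"]), kd_se = unname(se["kd"]),
    intercept_se = intercept_se,
    intercept_zero = if (fix_origin) NA else
      is.na(intercept_se) || abs(intercept) <= 2 * intercept_se,
    kd_reliable = kd_reliable), class = "lox_sat_fit")
}

#' @export
print.lox_sat_fit <- function(x, ...) {
  cat(sprintf("<lox_sat_fit> k_red = %.4g +/- %.2g /s, Kd = %.4g +/- %.2g M%s\n",
              x$k_red, x$k_red_se, x$kd, x$kd_se,
              if (isFALSE(x$kd_reliable)) " (kd unreliable)" else ""))
  if (!is.na(x$intercept) && x$intercept != 0)
    cat(sprintf("  intercept = %.4g +/- %.2g /s (zero within 2 se: %s)\n",
                x$intercept, x$intercept_se, x$intercept_zero))
  invisible(x)
}

#' Linear fit of reoxidation rates against oxygen concentration
#'
#' Ordinary least squares of `k_obs` on `[O2]`; the slope is the
#' second-order re-oxidation rate constant `k_ox`. A series whose slope is
#' not positive (or indistinguishable from zero) is flagged invalid for a
#' reoxidation experiment.
#'
#' @param points data.frame with columns `o2` (M) and `kobs` (s^-1)
#' @param relative_errors if `TRUE`, assume the `kobs` error is
#'   proportional to its value (weights `1/o2^2`), which calibrates the
#'   slope standard error when rates carry a constant coefficient of
#'   variation; default `FALSE` (ordinary least squares)
#' @return an object of class `lox_lin_fit`: `k_ox`, `intercept`, standard
#'   errors, `df` (residual degrees of freedom), `valid`
#' @export
fit_kox_linear <- function(points, relative_errors = FALSE) {
  stopifnot(is.data.frame(points), all(c("o2", "kobs") %in% names(points)))
  if (length(unique(points$o2)) < 3)
    lox_stop("need at least 3 distinct O2 concentrations", "lox_design_error")
  fit <- if (relative_errors)
    stats::lm(kobs ~ o2, data = points, weights = 1 / points$o2^2)
  else stats::lm(kobs ~ o2, data = points)
  cf <- stats::coef(fit)
  # suppress the "essentially perfect fit" note on noiseless input
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  slope <- unname(cf["o2"]); slope_se <- unname(se["o2"])
  valid <- is.finite(slope) && slope > 0 &&
    (slope_se == 0 || slope > 2 * slope_se)
  if (!valid)
    lox_warn("slope not distinguishable from zero: not a valid reoxidation series",
             "lox_invalid_series_warning")
  structure(list(k_ox = slope, intercept = unname(cf["(Intercept)"]),
                 k_ox_se = slope_se, intercept_se = unname(se["(Intercept)"]),
                 df = stats::df.residual(fit), valid = valid,
                 n = nrow(points)),
            class = "lox_lin_fit")
}

#' @export
print.lox_lin_fit <- function(x, ...) {
  cat(sprintf("<lox_lin_fit> k_ox = %.4g +/- %.2g /M/s (n = %d%s)\n",
              x$k_ox, x$k_ox_se, x$n,
              if (!x$valid) ", INVALID series" else ""))
  invisible(x)
}
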