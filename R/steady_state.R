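#' Michaelis-Menten fit of an initial-rate table
#'
#' Nonlinear least squares of `v/e0 = kcat_app * s / (km_S + s)` on a rate
#' table (replicates fitted jointly, unweighted). Starting values come from
#' a Hanes linearization. The catalytic efficiency `kcat_over_km` is
#' derived from the fitted parameters.
#'
#' @param table data.frame with columns `lactate_M` and `v_over_e0_per_s`
#'   (a `replicate` column is allowed and ignored by the fit)
#' @return an object of class `lox_mm_fit`: `kcat_app` (s^-1), `km_S` (M),
#'   standard errors, `kcat_over_km` (M^-1 s^-1), `km_reliable`
#' @export
fit_michaelis_menten <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("lactate_M", "v_over_e0_per_s") %in% names(table)))
  s <- table$lactate_M
  v <- table$v_over_e0_per_s
  if (length(unique(s)) < 6)
    lox_warn("fewer than 6 distinct substrate concentrations in the design",
             "lox_identifiability_warning")
  # Hanes: s/v = s/kcat + km/kcat
  hanes <- stats::lm(I(s / v) ~ s)
  kcat0 <- 1 / max(stats::coef(hanes)[2], 1e-12)
  km0 <- max(stats::coef(hanes)[1] * kcat0, min(s[s > 0]) / 10)
  fit <- lm_least_squares(
    function(p) v - p[["kcat"]] * s / (p[["km"]] + s),
    c(kcat = unname(kcat0), km = unname(km0)))
  cf <- fit$par
  se <- fit$se
  km <- unname(cf["km"]); km_se <- unname(se["km"])
  km_reliable <- is.finite(km_se) && km_se < km && max(s) >= km
  if (!km_reliable)
    lox_warn("km_S is not identifiable from this table (no saturation curvature)",
             "lox_identifiability_warning")
  structure(list(kcat_app = unname(cf["kcat"]), km_S = km,
                 kcat_app_se = unname(se["kcat"]), km_S_se = km_se,
                 kcat_over_km = unname(cf["kcat"]) / km,
                 km_reliable = km_reliable,
                 residual_sd = fit$residual_sd),
            class = "lox_mm_fit")
}

#' @export
print.lox_mm_fit <- function(x, ...) {
  cat(sprintf(paste0("<lox_mm_fit> kcat_app = %.4g +/- %.2g /s, ",
                     "Km = %.4g +/- %.2g M, kcat/Km = %.4g /M/s%s\n"),
              x$kcat_app, x$kcat_app_se, x$km_S, x$km_S_se, x$kcat_over_km,
              if (!x$km_reliable) " (Km unreliable)" else ""))
  invisible(x)
}

#' Catalytic efficiency in the units the field reports
#'
#' @param kcat_app apparent kcat (s^-1)
#' @param km_mM Michaelis constant in mM
#' @return kcat/Km in mM^-1 s^-1
#' @export
catalytic_efficiency_mM <- function(kcat_app, km_mM) {
  check_positive(kcat_app, "kcat_app"); check_positive(km_mM, "km_mM")
  kcat_app / km_mM
}

#' Derive the microscopic-parameter summary for one enzyme variant
#'
#' Composes the mechanism algebra into one record per variant: the pyruvate
#' release constant `k5` (from the reciprocal-sum relation with the
#' apparent kcat, or measured directly as a slow stopped-flow phase when
#' one is available), the turnover number at O2 saturation
#' `kcat_sat = k3*k5/(k3+k5)`, the Michaelis constant for oxygen
#' `km_O2 = kcat_sat/k7` (always from the derived `kcat_sat`, never from
#' the air-saturation kcat), and the per-step rate-limitation fractions at
#' the stated `o2`.
#'
#' If both a measured `k5` and the algebraic one are available the record
#' carries both, uses the measured one, and flags a disagreement greater
#' than 20%. An infeasible reciprocal-sum relation (apparent kcat exceeding
#' the `k3`/`k7*o2` cap) raises a `lox_infeasible` error rather than being
#' silently clipped.
#'
#' @param mm a [fit_michaelis_menten()] result, or a list with `kcat_app`
#'   and `km_S`
#' @param k3 FMN reduction rate constant (s^-1), from transient kinetics
#' @param kox FMN re-oxidation rate constant `k7` (M^-1 s^-1)
#' @param o2 oxygen concentration of the steady-state assay (M)
#' @param k5_measured optional directly measured slow-phase rate (s^-1)
#' @param label,ph variant annotation
#' @return an object of class `lox_variant_summary`
#' @export
derive_variant_summary <- function(mm, k3, kox, o2 = 250e-6,
                                   k5_measured = NULL,
                                   label = NA_character_, ph = NA_real_) {
  kcat_app <- mm$kcat_app
  check_positive(kcat_app, "kcat_app")
  k5_eq <- tryCatch(solve_k5_from_kcat(kcat_app, k3, kox, o2),
                    lox_infeasible = function(e) {
                      if (is.null(k5_measured)) stop(e)
                      NA_real_
                    })
  k5_source <- if (!is.null(k5_measured)) "measured" else "kcat_relation"
  k5 <- if (!is.null(k5_measured)) k5_measured else k5_eq
  if (!is.null(k5_measured) && is.finite(k5_eq) &&
      abs(k5_measured - k5_eq) > 0.2 * k5_eq)
    lox_warn(sprintf(paste0("measured k5 (%.3g /s) and kcat-derived k5 ",
                            "(%.3g /s) disagree by more than 20%%"),
                     k5_measured, k5_eq), "lox_k5_disagreement")
  kcat_sat <- kcat_saturating(k3, k5)
  structure(list(label = label, ph = ph,
                 kcat_app = kcat_app, km_S = mm$km_S,
                 kcat_over_km = kcat_app / mm$km_S,
                 k3 = k3, k5 = k5, k5_eq1 = k5_eq, k5_source = k5_source,
                 kox = kox, o2 = o2,
                 kcat_sat = kcat_sat,
                 km_O2 = km_oxygen(kcat_sat, kox),
                 rate_limit_fractions =
                   rate_limitation_fractions(k3, k5, kox, o2)),
            class = "lox_variant_summary")
}

#' @export
print.lox_variant_summary <- function(x, ...) {
  cat(sprintf("<lox_variant_summary> %s (pH %s)\n",
              ifelse(is.na(x$label), "unlabelled", x$label),
              ifelse(is.na(x$ph), "?", format(x$ph))))
  cat(sprintf("  kcat_app = %.3g /s at [O2] = %.3g M; Km(S) = %.3g M\n",
              x$kcat_app, x$o2, x$km_S))
  cat(sprintf("  k3 = %.3g /s, k5 = %.3g /s (%s), k7 = %.3g /M/s\n",
              x$k3, x$k5, x$k5_source, x$kox))
  cat(sprintf("  kcat(O2-sat) = %.3g /s, Km(O2) = %.3g uM\n",
              x$kcat_sat, 1e6 * x$km_O2))
  fr <- round(100 * x$rate_limit_fractions)
  cat(sprintf("  rate limitation: k3 %d%%, k5 %d%%, k7[O2] %d%%\n",
              fr[1], fr[2], fr[3]))
  invisible(x)
}

#' Fold-change report across enzyme variants
#'
#' For each kinetic parameter, the ratio reference/variant (so a slowed
#' variant shows a fold decrease > 1). Exact ratios are kept in `ratio`;
#' `fold` rounds to 2 significant figures for display, following the
#' convention of reporting rates to 2 significant figures. Parameters
#' missing in either record are omitted (listed in the `omitted`
#' attribute).
#'
#' @param summaries list of [derive_variant_summary()] records (or lists
#'   with the same fields)
#' @param reference label of the reference variant
#' @return data.frame with columns `variant`, `parameter`, `ratio`, `fold`
#' @export
compare_variants <- function(summaries, reference) {
  labels <- vapply(summaries, function(s) s$label, "")
  if (!reference %in% labels)
    stop_invalid_input(sprintf("reference '%s' not among summaries", reference))
  if (length(summaries) < 2)
    lox_warn("only one summary supplied: no ratios to report",
             "lox_design_warning")
  phs <- vapply(summaries, function(s) s$ph %||% NA_real_, 1.0)
  if (length(unique(phs[!is.na(phs)])) > 1)
    lox_warn("summaries span multiple pH values: folds mix conditions",
             "lox_design_warning")
  ref <- summaries[[match(reference, labels)]]
  params <- c("kcat_app", "km_S", "kcat_over_km", "k3", "k5", "kox",
              "kcat_sat", "km_O2")
  rows <- list(); omitted <- character(0)
  for (s in summaries) {
    if (identical(s$label, reference)) next
    for (p in params) {
      rv <- ref[[p]]; vv <- s[[p]]
      if (is.null(rv) || is.null(vv) || !is.finite(rv) || !is.finite(vv)) {
        omitted <- c(omitted, paste0(s$label, ":", p))
        next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(variant = s$label, parameter = p, ratio = rv / vv,
                   fold = signif(rv / vv, 2))
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(variant = character(0), parameter = character(0),
               ratio = numeric(0), fold = numeric(0))
  attr(out, "reference") <- reference
  attr(out, "omitted") <- omitted
  out
}
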