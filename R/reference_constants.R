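#' Published kinetic constants for wild-type lactate oxidase and Tyr215
#' variants
#'
#' The stopped-flow and steady-state constants reported for
#' *Aerococcus viridans* lactate oxidase (wild type, Y215F, Y215H) across
#' reaction pH. These printed values are inputs to the analysis (generating
#' truths for synthetic experiments, and the constants entering the
#' turnover algebra); they are not fitted here.
#'
#' Columns: `variant`, `ph`; transient constants `k_red` (= `k3`, s^-1),
#' `kd_mM` (apparent lactate dissociation constant), `k_slow` (second
#' 455 nm phase, s^-1, where observed), `k_ox` (= `k7`, M^-1 s^-1);
#' steady-state `kcat_app` (s^-1 at 250 uM O2) and `km_mM`; the derived
#' `k5` (s^-1; measured or from the kcat relation, as published) and the
#' published pseudo-first-order `k7_o2` (s^-1 at 250 uM O2, kept verbatim —
#' for wild type at pH 9.5 the printed 162 s^-1 differs slightly from
#' `k_ox * 250e-6`). `ct_band` marks variants with an observable 530 nm
#' charge-transfer band during reduction.
#'
#' @return a data.frame, one row per variant x pH
#' @export
lox_reference_constants <- function() {
  data.frame(
    variant = rep(c("wild-type", "Y215F", "Y215H"), each = 3),
    ph      = rep(c(5.5, 6.5, 9.5), times = 3),
    k_red   = c(170, 270, 230,   62, 120, 85,   7.2, 8.2, 8.7),
    kd_mM   = c(3.0, 1.0, 1.5,   NA, 0.28, NA,  2.3, 0.55, 0.20),
    k_slow  = c(NA,  NA,  5.3,   12, 20,  20,   NA,  NA,  NA),
    k_ox    = c(1.1e6, 1.8e6, 6.0e5,  NA, 7.0e5, NA,  NA, 1.0e5, NA),
    kcat_app = c(NA, 88, 4.1,    NA, 22, NA,    NA, 5.0, NA),
    km_mM   = c(NA, 0.50, NA,    NA, 0.13, NA,  NA, 0.52, NA),
    k5      = c(57, 141, 5.3,    12, 20,  20,   NA, 26, NA),
    k7_o2   = c(275, 450, 162,   NA, 175, NA,   NA, 25, NA),
    ct_band = rep(c(FALSE, TRUE, FALSE), each = 3)
  )
}

#' Rate-constant set for a published variant/pH condition
#'
#' Convenience constructor assembling a [lox_rates()] object from the
#' published constants: `k3 = k_red`, `k5` as published (slow phase or
#' kcat-derived), `k7 = k_ox`, and rapid-equilibrium binding with
#' `k2 = kd * k1`.
#'
#' @param variant "wild-type", "Y215F" or "Y215H"
#' @param ph 5.5, 6.5 or 9.5
#' @param k1 association rate constant (M^-1 s^-1)
#' @return a [lox_rates()] object
#' @export
lox_reference_rates <- function(variant, ph = 6.5, k1 = 1e8) {
  tab <- lox_reference_constants()
  row <- tab[tab$variant == variant & tab$ph == ph, ]
  if (nrow(row) != 1)
    stop_invalid_input(sprintf("no reference constants for %s at pH %s",
                               variant, format(ph)))
  for (col in c("k_red", "kd_mM", "k5", "k_ox")) {
    if (is.na(row[[col]]))
      stop_invalid_input(sprintf("reference `%s` not reported for %s at pH %s",
                                 col, variant, format(ph)))
  }
  lox_rates(k1 = k1, kd = row$kd_mM * 1e-3, k3 = row$k_red, k5 = row$k5,
            k7 = row$k_ox, label = variant, ph = ph)
}

#' Default optical model for a published variant
#'
#' Wild type and Y215F show the 530 nm charge-transfer band of the reduced
#' enzyme-pyruvate complex; Y215H does not, which is reproduced by zeroing
#' its 530 nm extinction coefficient.
#'
#' @inheritParams lox_reference_rates
#' @return a [lox_optics()] object
#' @export
lox_reference_optics <- function(variant) {
  tab <- lox_reference_constants()
  ct <- tab$ct_band[match(variant, tab$variant)]
  if (is.na(ct))
    stop_invalid_input(sprintf("unknown variant '%s'", variant))
  if (ct) lox_optics() else
    lox_optics(eps530 = c(E_ox = 0, E_ox_S = 0, E_red_P = 0, E_red = 0))
}
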