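#!/usr/bin/env Rscript
# Stage 2: stopped-flow (pre-steady-state) analysis.
#
# For each variant, fit the 455 nm reduction traces with single/double
# exponentials (phase-detection rule), the fast-phase k_obs against
# lactate with a hyperbola (k_red, K_d), the slow phase as the
# concentration-independent pyruvate release rate, the reoxidation k_obs
# against [O2] with a line through k_ox, and — where the 530 nm
# charge-transfer band is visible — the full ODE scheme against the 530 nm
# trace (k3, k5). Writes a per-variant transient-parameter summary to
# results/analysis/transient_parameters.csv.

suppressPackageStartupMessages(library(loxkin))

out <- "results/analysis"
variants <- c("wild-type", "Y215F", "Y215H")

rows <- list()
for (v in variants) {
  red <- read_traces(file.path(out, "traces", paste0(v, "_reduction.csv")))
  reox <- read_traces(file.path(out, "traces", paste0(v, "_reoxidation.csv")))
  rates <- read_lox_rates(file.path(out, "tables", paste0(v, "_truth.json")))
  optics <- lox_reference_optics(v)

  tf <- fit_transient_experiments(red, reox, rates, optics)
  jsonlite::write_json(
    list(k_red_per_s = tf$sat$k_red, k_red_se = tf$sat$k_red_se,
         kd_M = tf$sat$kd, kd_se = tf$sat$kd_se,
         k_slow_per_s = tf$k_slow,
         k_ox_per_M_per_s = tf$lin$k_ox, k_ox_se = tf$lin$k_ox_se,
         ct = if (is.null(tf$ct)) NULL else
           list(k3_per_s = tf$ct$k3, k5_per_s = tf$ct$k5),
         kobs = tf$kobs),
    file.path(out, paste0(v, "_transient.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  rows[[v]] <- data.frame(
    variant = v,
    k_red_per_s = tf$sat$k_red, kd_mM = 1e3 * tf$sat$kd,
    k_slow_per_s = if (is.null(tf$k_slow)) NA_real_ else tf$k_slow,
    k_ox_per_M_per_s = tf$lin$k_ox,
    ct_k3_per_s = if (is.null(tf$ct)) NA_real_ else tf$ct$k3,
    ct_k5_per_s = if (is.null(tf$ct)) NA_real_ else tf$ct$k5)

  cat(sprintf("%-10s  k_red %6.1f /s  Kd %5.3f mM  k_slow %s  k_ox %.3g /M/s  CT(k3,k5) %s\n",
              v, tf$sat$k_red, 1e3 * tf$sat$kd,
              if (is.null(tf$k_slow)) "  n.a." else
                sprintf("%5.1f", tf$k_slow),
              tf$lin$k_ox,
              if (is.null(tf$ct)) "n.a." else
                sprintf("(%.0f, %.1f)", tf$ct$k3, tf$ct$k5)))
}
tab <- do.call(rbind, rows)
write.csv(tab, file.path(out, "transient_parameters.csv"), row.names = FALSE)
cat("wrote", file.path(out, "transient_parameters.csv"), "\n")
cat("note: wild type at 20 C / pH 6.5 has k5 within 2-fold of k3, so the\n",
    "455 nm phases merge and k_red is a blended underestimate — the same\n",
    "limitation the stopped-flow experiment itself faces.\n")
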