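#!/usr/bin/env Rscript
# Stage 1: generate the in-silico study data.
#
# For wild-type lactate oxidase and the two Tyr215 variants (pH 6.5), with
# the published stopped-flow constants as generating truths, simulate
#   - anaerobic reduction stopped-flow traces (455 nm FMN bleach, 530 nm
#     charge-transfer band) over a lactate series,
#   - reoxidation traces (455 nm rise) over an O2 series,
#   - steady-state initial-rate tables at air saturation (250 uM O2),
# all through the instrument model (1.5 ms dead time, 0.5 ms sampling,
# 1 mAU noise). Outputs go to results/analysis/{traces,tables}.

suppressPackageStartupMessages(library(loxkin))

out <- "results/analysis"
dir.create(file.path(out, "traces"), recursive = TRUE, showWarnings = FALSE)
dir.create(file.path(out, "tables"), recursive = TRUE, showWarnings = FALSE)

base_seed <- 20160615L
lactate_mM <- c(0.25, 0.5, 1, 2, 5, 10)
o2_uM <- c(60, 125, 250, 500)
rate_lactate_mM <- c(0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10)

variants <- c("wild-type", "Y215F", "Y215H")
for (i in seq_along(variants)) {
  v <- variants[i]
  rates <- lox_reference_rates(v)
  optics <- lox_reference_optics(v)
  kd <- rates$k2 / rates$k1

  # observation windows long enough for the slowest phase to complete
  t_red <- 7 / min(kobs_saturation_value(min(lactate_mM) * 1e-3, rates$k3, kd),
                   rates$k5)
  t_reox <- 7 / (rates$k7 * min(o2_uM) * 1e-6)

  red <- simulate_reduction_experiment(
    rates, optics, lox_instrument(seed = base_seed + 10L * i),
    e0 = 5e-6, lactate_concs = lactate_mM * 1e-3, t_end = t_red)
  reox <- simulate_reoxidation_experiment(
    rates, optics, lox_instrument(seed = base_seed + 10L * i + 1L),
    e0 = 5e-6, o2_concs = o2_uM * 1e-6, t_end = t_reox)
  tab <- simulate_initial_rate_table(
    rates, e0 = 5e-8, lactate_concs = rate_lactate_mM * 1e-3, o2 = 250e-6,
    replicates = 3, noise_cv = 0.03, seed = base_seed + 10L * i + 2L)

  write_traces(red, file.path(out, "traces", paste0(v, "_reduction.csv")))
  write_traces(reox, file.path(out, "traces", paste0(v, "_reoxidation.csv")))
  write.csv(tab, file.path(out, "tables", paste0(v, "_rates.csv")),
            row.names = FALSE)
  write_lox_rates(rates, file.path(out, "tables", paste0(v, "_truth.json")))
  cat(sprintf("%-10s  %d reduction traces (t_end %.2f s), %d reoxidation traces, %d-point rate table\n",
              v, length(red), t_red, length(reox), nrow(tab)))
}
cat("wrote", out, "\n")
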