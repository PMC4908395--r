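#' Read and validate an experiment configuration
#'
#' The configuration is a YAML (or JSON) document describing the whole
#' in-silico study: instrument block, experimental designs (lactate series,
#' O2 series, rate-table design), and one block per enzyme variant with its
#' rate constants and optional optics overrides. All concentrations and
#' times carry explicit unit suffixes in their key names (`_mM`, `_uM`,
#' `_M`, `_s`, `_per_s`, `_per_M_per_s`, `_per_M_cm`, `_AU`); unknown keys
#' are rejected, and a seed is mandatory because the simulated stages are
#' stochastic.
#'
#' @param path path to the YAML/JSON configuration file
#' @return a validated config object (named list) of class `lox_config`
#' @export
read_experiment_config <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE) else yaml::read_yaml(path)
  validate_experiment_config(doc)
}

# YAML leaves like "1.8e6" arrive as strings (YAML 1.1 exponent syntax);
# coerce any leaf that parses fully as numeric, except label-like keys.
coerce_config_numbers <- function(x, key = "") {
  if (is.list(x)) {
    for (nm in seq_along(x))
      x[[nm]] <- coerce_config_numbers(x[[nm]],
                                       key = names(x)[nm] %||% "")
    return(x)
  }
  if (is.character(x) && !key %in% c("label", "reference")) {
    y <- suppressWarnings(as.numeric(x))
    if (!any(is.na(y))) return(y)
  }
  x
}

config_check_keys <- function(block, allowed, required, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra) > 0)
    lox_stop(sprintf("unknown key(s) in %s: %s", where,
                     paste(extra, collapse = ", ")), "lox_config_error")
  missing <- setdiff(required, names(block))
  if (length(missing) > 0)
    lox_stop(sprintf("missing required key(s) in %s: %s", where,
                     paste(missing, collapse = ", ")), "lox_config_error")
  invisible(block)
}

#' @rdname read_experiment_config
#' @param doc a configuration list (as parsed from YAML/JSON)
#' @export
validate_experiment_config <- function(doc) {
  doc <- coerce_config_numbers(doc)
  config_check_keys(doc, c("seed", "instrument", "designs", "variants",
                           "reference"),
                    c("seed", "designs", "variants"), "config")
  if (!is.numeric(doc$seed)) lox_stop("`seed` must be an integer",
                                      "lox_config_error")
  inst <- doc$instrument
  if (is.null(inst)) inst <- list()
  config_check_keys(inst, c("dead_time_s", "sample_interval_s",
                            "noise_sd_AU"), character(0), "instrument")
  config_check_keys(doc$designs, c("reduction", "reoxidation", "rate_table"),
                    c("reduction", "reoxidation", "rate_table"), "designs")
  config_check_keys(doc$designs$reduction, c("e0_uM", "lactate_mM", "t_end_s"),
                    c("e0_uM", "lactate_mM"), "designs$reduction")
  config_check_keys(doc$designs$reoxidation, c("e0_uM", "o2_uM", "t_end_s"),
                    c("e0_uM", "o2_uM"), "designs$reoxidation")
  config_check_keys(doc$designs$rate_table,
                    c("e0_nM", "lactate_mM", "o2_uM", "replicates",
                      "noise_cv"),
                    c("e0_nM", "lactate_mM", "o2_uM"), "designs$rate_table")
  if (is.data.frame(doc$variants))
    lox_stop("`variants` must be a list of blocks", "lox_config_error")
  for (i in seq_along(doc$variants)) {
    vb <- doc$variants[[i]]
    where <- sprintf("variants[%d]", i)
    config_check_keys(vb, c("label", "ph", "rates", "optics"),
                      c("label", "rates"), where)
    config_check_keys(vb$rates,
                      c("k1_per_M_per_s", "k2_per_s", "kd_mM", "k3_per_s",
                        "k4_per_s", "k5_per_s", "k6_per_M_per_s",
                        "k7_per_M_per_s"),
                      c("k3_per_s", "k5_per_s", "k7_per_M_per_s"),
                      paste0(where, "$rates"))
    if (is.null(vb$rates$k2_per_s) && is.null(vb$rates$kd_mM))
      lox_stop(sprintf("%s$rates needs k2_per_s or kd_mM", where),
               "lox_config_error")
    if (!is.null(vb$optics))
      config_check_keys(vb$optics,
                        c("path_length_cm", "eps455_E_red_P_per_M_cm",
                          "eps455_E_red_per_M_cm", "eps530_E_red_P_per_M_cm"),
                        character(0), paste0(where, "$optics"))
  }
  structure(doc, class = "lox_config")
}

config_rates <- function(vb) {
  r <- vb$rates
  lox_rates(k1 = r$k1_per_M_per_s %||% 1e8,
            k2 = r$k2_per_s,
            kd = if (is.null(r$kd_mM)) NULL else r$kd_mM * 1e-3,
            k3 = r$k3_per_s, k4 = r$k4_per_s %||% 0,
            k5 = r$k5_per_s, k6 = r$k6_per_M_per_s %||% 0,
            k7 = r$k7_per_M_per_s,
            label = vb$label, ph = vb$ph %||% NA_real_)
}

config_optics <- function(vb) {
  o <- vb$optics %||% list()
  eps455 <- c(E_ox = 12500, E_ox_S = 12500,
              E_red_P = o$eps455_E_red_P_per_M_cm %||% 1250,
              E_red = o$eps455_E_red_per_M_cm %||% 0)
  eps530 <- c(E_ox = 0, E_ox_S = 0,
              E_red_P = o$eps530_E_red_P_per_M_cm %||% 1500, E_red = 0)
  lox_optics(path_length = o$path_length_cm %||% 1,
             eps455 = eps455, eps530 = eps530)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full simulate / fit-transient / fit-steady / derive / compare
#' pipeline
#'
#' Executes the whole in-silico study described by a configuration:
#' simulates stopped-flow reduction and reoxidation experiments and
#' steady-state rate tables for every variant, fits them with the package's
#' transient and steady-state fitters, derives the per-variant
#' microscopic-parameter summary, and reports fold changes against the
#' reference variant. All randomness is seeded from the config seed, so a
#' rerun with the same config gives identical machine outputs. Every stage
#' writes its artifacts under `out_dir` (trace CSVs, fit JSONs, summary
#' CSV/JSON, fold-change CSV, plain-text log).
#'
#' @param config a `lox_config` (from [read_experiment_config()]) or a path
#'   to a config file
#' @param out_dir output directory (created if absent)
#' @param seed optional override of the config seed
#' @return (invisibly) a list with `summaries`, `transient_fits`,
#'   `steady_fits`, `folds`, and `files`
#' @export
run_lox_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_experiment_config(config)
  config <- validate_experiment_config(unclass(config))
  base_seed <- as.integer(seed %||% config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("traces", "fits", "tables", "summary"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  logf <- file.path(out_dir, "pipeline.log")
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(config), cfg_file)
  cat(sprintf("loxkin %s pipeline\nconfig md5 %s\nseed %d\n",
              as.character(utils::packageVersion("loxkin")),
              unname(tools::md5sum(cfg_file)), base_seed),
      file = logf)
  stage_log <- function(stage, t0)
    cat(sprintf("stage %-14s %8.2f s\n", stage,
                as.numeric(Sys.time()) - t0), file = logf, append = TRUE)

  inst0 <- config$instrument %||% list()
  mk_inst <- function(seed) lox_instrument(
    dead_time = inst0$dead_time_s %||% 1.5e-3,
    sample_interval = inst0$sample_interval_s %||% 5e-4,
    noise_sd = inst0$noise_sd_AU %||% 1e-3, seed = seed)

  des <- config$designs
  files <- character(0)
  transient_fits <- list(); steady_fits <- list(); summaries <- list()

  for (i in seq_along(config$variants)) {
    vb <- config$variants[[i]]
    rates <- config_rates(vb)
    optics <- config_optics(vb)
    label <- vb$label
    t0 <- as.numeric(Sys.time())

    ## --- simulate ---------------------------------------------------------
    red_e0 <- des$reduction$e0_uM * 1e-6
    s_series <- des$reduction$lactate_mM * 1e-3
    kd <- rates$k2 / rates$k1
    kobs_min <- min(kobs_saturation_value(min(s_series), rates$k3, kd),
                    rates$k5)
    t_red <- des$reduction$t_end_s %||% (7 / kobs_min)
    red <- simulate_reduction_experiment(rates, optics, mk_inst(base_seed + 10L * i),
                                         red_e0, s_series, t_red)
    o2_series <- des$reoxidation$o2_uM * 1e-6
    t_reox <- des$reoxidation$t_end_s %||% (7 / (rates$k7 * min(o2_series)))
    reox <- simulate_reoxidation_experiment(rates, optics,
                                            mk_inst(base_seed + 10L * i + 1L),
                                            des$reoxidation$e0_uM * 1e-6,
                                            o2_series, t_reox)
    tab <- simulate_initial_rate_table(rates,
                                       e0 = des$rate_table$e0_nM * 1e-9,
                                       lactate_concs = des$rate_table$lactate_mM * 1e-3,
                                       o2 = des$rate_table$o2_uM * 1e-6,
                                       replicates = des$rate_table$replicates %||% 3,
                                       noise_cv = des$rate_table$noise_cv %||% 0.03,
                                       seed = base_seed + 10L * i + 2L)
    f_red <- file.path(out_dir, "traces", paste0(label, "_reduction.csv"))
    f_reox <- file.path(out_dir, "traces", paste0(label, "_reoxidation.csv"))
    f_tab <- file.path(out_dir, "tables", paste0(label, "_rates.csv"))
    write_traces(red, f_red); write_traces(reox, f_reox)
    utils::write.csv(tab, f_tab, row.names = FALSE)
    files <- c(files, f_red, f_reox, f_tab)
    stage_log(paste0("simulate:", label), t0)

    ## --- fit-transient ----------------------------------------------------
    t0 <- as.numeric(Sys.time())
    tf <- fit_transient_experiments(red, reox, rates, optics)
    transient_fits[[label]] <- tf
    f_fit <- file.path(out_dir, "fits", paste0(label, "_transient.json"))
    jsonlite::write_json(transient_report(tf), f_fit, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files <- c(files, f_fit)
    stage_log(paste0("fit-transient:", label), t0)

    ## --- fit-steady -------------------------------------------------------
    t0 <- as.numeric(Sys.time())
    mm <- fit_michaelis_menten(tab)
    steady_fits[[label]] <- mm
    f_mm <- file.path(out_dir, "fits", paste0(label, "_steady.json"))
    jsonlite::write_json(list(kcat_app_per_s = mm$kcat_app,
                              km_S_M = mm$km_S,
                              kcat_over_km_per_M_per_s = mm$kcat_over_km),
                         f_mm, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, f_mm)
    stage_log(paste0("fit-steady:", label), t0)

    ## --- derive -----------------------------------------------------------
    t0 <- as.numeric(Sys.time())
    summaries[[label]] <- derive_variant_summary(
      mm, k3 = tf$sat$k_red, kox = tf$lin$k_ox,
      o2 = des$rate_table$o2_uM * 1e-6,
      k5_measured = tf$k_slow, label = label, ph = vb$ph %||% NA_real_)
    stage_log(paste0("derive:", label), t0)
  }

  ## summary table + compare ------------------------------------------------
  sum_df <- do.call(rbind, lapply(summaries, function(s) data.frame(
    variant = s$label, ph = s$ph, kcat_app_per_s = s$kcat_app,
    km_S_mM = 1e3 * s$km_S, k3_per_s = s$k3, k5_per_s = s$k5,
    k5_source = s$k5_source, k7_per_M_per_s = s$kox,
    kcat_sat_per_s = s$kcat_sat, km_O2_uM = 1e6 * s$km_O2,
    frac_k3 = s$rate_limit_fractions[["k3"]],
    frac_k5 = s$rate_limit_fractions[["k5"]],
    frac_k7o2 = s$rate_limit_fractions[["k7_o2"]])))
  f_sum <- file.path(out_dir, "summary", "variant_summary.csv")
  utils::write.csv(sum_df, f_sum, row.names = FALSE)
  f_sumj <- file.path(out_dir, "summary", "variant_summary.json")
  jsonlite::write_json(lapply(summaries, unclass), f_sumj,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, f_sum, f_sumj)
  folds <- NULL
  if (!is.null(config$reference) && length(summaries) > 1) {
    folds <- compare_variants(unname(summaries), config$reference)
    f_cmp <- file.path(out_dir, "summary", "fold_changes.csv")
    utils::write.csv(folds, f_cmp, row.names = FALSE)
    files <- c(files, f_cmp)
  }
  invisible(list(summaries = summaries, transient_fits = transient_fits,
                 steady_fits = steady_fits, folds = folds, files = files))
}

#' Transient-fitting stage over one variant's stopped-flow experiments
#'
#' Runs the complete stopped-flow analysis protocol on a set of reduction
#' and reoxidation traces: per-trace exponential fits with the
#' phase-detection rule, aggregation of the concentration-independent slow
#' rate over traces where the phases are separable (with fixed-slow-rate
#' refits elsewhere), the hyperbolic k_obs-lactate fit (`k_red`, `K_d`),
#' the linear k_obs-O2 fit (`k_ox`), and — when a 530 nm charge-transfer
#' band is present — the combined ODE simulation-and-fitting of the
#' highest-lactate 530 nm trace (`k3`, `k5`). `rates` supplies the fixed
#' binding constants (`k1`, `k2`) for the ODE fit; its initial guesses are
#' taken from the 455 nm analysis.
#'
#' @param red reduction `lox_trace_set` (455 and 530 nm)
#' @param reox reoxidation `lox_trace_set` (455 nm)
#' @param rates a [lox_rates()] carrying the fixed (non-fitted) constants
#' @param optics a [lox_optics()] object
#' @return list with `kobs` (per-trace table), `sat` (`lox_sat_fit`),
#'   `k_slow`, `reox_kobs`, `lin` (`lox_lin_fit`), `ct` (`lox_ct_fit` or
#'   `NULL`)
#' @export
fit_transient_experiments <- function(red, reox, rates, optics) {
  red455 <- Filter(function(tr) tr$wavelength == 455, red)
  kobs <- do.call(rbind, lapply(red455, function(tr) {
    ef <- fit_exponentials(tr, max_phases = 2)
    data.frame(s = tr$meta$lactate_M,
               kobs_fast = ef$phases$rate[1],
               kobs_slow = if (ef$n_phases == 2) ef$phases$rate[2] else NA_real_,
               n_phases = ef$n_phases)
  }))
  # The slow rate is concentration-independent, so it is averaged — but
  # only over concentrations where the two phases are genuinely separated
  # (fast rate at least 3-fold above the provisional slow median);
  # borderline traces are refitted with the slow rate fixed so that the
  # fast rate is not biased by an unresolved slow component.
  k_slow <- NULL
  if (any(!is.na(kobs$kobs_slow))) {
    k_slow_med <- stats::median(kobs$kobs_slow, na.rm = TRUE)
    resolved <- !is.na(kobs$kobs_slow) & kobs$kobs_fast >= 3 * k_slow_med
    if (any(resolved)) {
      k_slow <- mean(kobs$kobs_slow[resolved])
      for (i in which(!resolved)) {
        ef <- tryCatch(fit_exponentials(red455[[i]], fix_slow_rate = k_slow),
                       error = function(e) NULL)
        if (!is.null(ef) && ef$phases$rate[1] > 1.5 * k_slow)
          kobs$kobs_fast[i] <- ef$phases$rate[1]
        kobs$kobs_slow[i] <- NA_real_
      }
    }
  }
  sat <- fit_kobs_saturation(data.frame(s = kobs$s, kobs = kobs$kobs_fast))

  okobs <- do.call(rbind, lapply(reox, function(tr) {
    ef <- fit_exponentials(tr, max_phases = 1)
    data.frame(o2 = tr$meta$o2_M, kobs = ef$phases$rate[1])
  }))
  lin <- fit_kox_linear(okobs)

  ct <- NULL
  red530 <- Filter(function(tr) tr$wavelength == 530, red)
  if (length(red530) > 0) {
    smax <- which.max(vapply(red530, function(tr) tr$meta$lactate_M, 1.0))
    init <- rates
    init$k3 <- sat$k_red
    init$k5 <- k_slow %||% (sat$k_red / 5)
    ct <- tryCatch(fit_ct_trace_ode(red530[[smax]], init, optics),
                   lox_no_intermediate = function(e) NULL)
  }
  list(kobs = kobs, sat = sat, k_slow = k_slow, reox_kobs = okobs,
       lin = lin, ct = ct)
}

transient_report <- function(tf) {
  list(
    k_red_per_s = tf$sat$k_red, k_red_se = tf$sat$k_red_se,
    kd_M = tf$sat$kd, kd_se = tf$sat$kd_se,
    k_slow_per_s = tf$k_slow,
    k_ox_per_M_per_s = tf$lin$k_ox, k_ox_se = tf$lin$k_ox_se,
    ct_fit = if (is.null(tf$ct)) NULL else
      list(k3_per_s = tf$ct$k3, k3_se = tf$ct$k3_se,
           k5_per_s = tf$ct$k5, k5_se = tf$ct$k5_se),
    binding_assumption = "k1, k2 fixed at rapid-equilibrium defaults",
    kobs_table = tf$kobs)
}
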