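test_that("charge-transfer trace peaks at the consecutive-reaction peak time", {
  # fast binding + (k3 = 150, k5 = 17): peak of the intermediate at
  # ln(k3/k5)/(k3 - k5) ~ 16.4 ms
  rates <- lox_rates(kd = 0.28e-3, k3 = 150, k5 = 17, k7 = 7e5)
  tset <- simulate_reduction_experiment(rates, lox_optics(),
                                        noiseless_instrument(),
                                        e0 = 4.3e-6, lactate_concs = 1e-2,
                                        t_end = 0.4)
  tr530 <- Filter(function(tr) tr$wavelength == 530, tset)[[1]]
  t_peak <- tr530$time[which.max(tr530$absorbance)]
  expect_lt(abs(t_peak - log(150 / 17) / (150 - 17)), 1e-3)
  # rise-then-fall shape
  expect_gt(max(tr530$absorbance), 10 * tr530$absorbance[length(tr530$time)])
})

test_that("total 455 nm amplitude is the Beer-Lambert difference of end states", {
  rates <- lox_reference_rates("Y215F")
  optics <- lox_optics()
  e0 <- 5e-6
  inst <- lox_instrument(noise_sd = 1e-3, seed = 7)
  amp_expected <- e0 * optics$path_length *
    (optics$eps[["455"]][["E_ox"]] - optics$eps[["455"]][["E_red"]])
  # noiseless completion amplitude: initial absorbance (all oxidized) minus
  # the final level matches the Beer-Lambert difference within 3 * noise_sd
  tset0 <- simulate_reduction_experiment(rates, optics,
                                         noiseless_instrument(), e0,
                                         lactate_concs = 1e-2, t_end = 0.6)
  tr0 <- Filter(function(x) x$wavelength == 455, tset0)[[1]]
  a_start <- e0 * optics$eps[["455"]][["E_ox"]]
  expect_lt(abs((a_start - tr0$absorbance[length(tr0$time)]) - amp_expected),
            3 * inst$noise_sd)
})

test_that("traces are reproducible by seed and differ across seeds only by noise", {
  rates <- lox_reference_rates("Y215F")
  optics <- lox_optics()
  run <- function(seed) simulate_reduction_experiment(
    rates, optics, lox_instrument(seed = seed), 5e-6, c(1e-3, 1e-2), 0.3)
  a <- run(5); b <- run(5); c <- run(6)
  expect_identical(a[[1]]$absorbance, b[[1]]$absorbance)
  expect_identical(a[[4]]$absorbance, b[[4]]$absorbance)
  d <- a[[1]]$absorbance - c[[1]]$absorbance
  expect_false(all(d == 0))
  expect_lt(max(abs(d)), 10 * 1e-3)   # differ only within noise
})

test_that("reoxidation is a single exponential with rate k7*[O2]", {
  rates <- lox_reference_rates("wild-type")
  optics <- lox_optics()
  tset <- simulate_reoxidation_experiment(rates, optics,
                                          noiseless_instrument(), 5e-6,
                                          o2_concs = 250e-6, t_end = 0.03)
  ef <- fit_exponentials(tset[[1]], max_phases = 1)
  expect_rel_equal(ef$phases$rate[1], 1.8e6 * 250e-6, 0.001)

  # an O2-free mix gives a flat trace
  flat <- simulate_reoxidation_experiment(rates, optics,
                                          noiseless_instrument(), 5e-6,
                                          o2_concs = 0, t_end = 0.03)
  expect_error(fit_exponentials(flat[[1]]), class = "lox_no_signal")

  # fitted rates across an O2 series lie on a line through the origin
  series <- simulate_reoxidation_experiment(rates, optics,
                                            noiseless_instrument(), 5e-6,
                                            o2_concs = o2_series,
                                            t_end = 0.12)
  kobs <- vapply(series, function(tr)
    fit_exponentials(tr, max_phases = 1)$phases$rate[1], 1.0)
  lf <- fit_kox_linear(data.frame(o2 = o2_series, kobs = kobs))
  expect_rel_equal(lf$k_ox, 1.8e6, 0.005)
  expect_lt(abs(lf$intercept), 0.005 * max(kobs))
})

test_that("initial-rate tables reproduce the turnover algebra", {
  rates <- lox_reference_rates("Y215H")
  # saturating lactate: v/e0 matches the reciprocal-sum kcat within 2%
  tab <- simulate_initial_rate_table(rates, lactate_concs = 0.1,
                                     replicates = 1, noise_cv = 0)
  expect_rel_equal(tab$v_over_e0_per_s, kcat_apparent(8.2, 26, 1e5, 250e-6),
                   0.02)
  expect_rel_equal(tab$v_over_e0_per_s, 5.0, 0.03)
  # v/e0 is invariant to enzyme concentration
  tab2 <- simulate_initial_rate_table(rates, e0 = 1e-7, lactate_concs = 0.1,
                                      replicates = 1, noise_cv = 0)
  expect_rel_equal(tab2$v_over_e0_per_s, tab$v_over_e0_per_s, 1e-3)
  # a window that cannot reach steady state before consuming 5% substrate
  expect_error(simulate_initial_rate_table(rates, e0 = 5e-6,
                                           lactate_concs = 5e-5,
                                           replicates = 1, noise_cv = 0),
               class = "lox_window_too_long")
})

test_that("noiseless traces are invariant to sampling refinement", {
  rates <- lox_reference_rates("Y215F")
  optics <- lox_optics()
  coarse <- simulate_reduction_experiment(
    rates, optics, lox_instrument(noise_sd = 0, sample_interval = 1e-3),
    5e-6, 2e-3, 0.2)
  fine <- simulate_reduction_experiment(
    rates, optics, lox_instrument(noise_sd = 0, sample_interval = 2.5e-4),
    5e-6, 2e-3, 0.2)
  i <- match(coarse[[1]]$time, fine[[1]]$time)
  expect_true(all(!is.na(i)))
  expect_lt(max(abs(coarse[[1]]$absorbance - fine[[1]]$absorbance[i])) /
              max(coarse[[1]]$absorbance), 1e-6)
})

test_that("530 nm absorbance tracks the reduced enzyme-pyruvate complex alone", {
  rates <- lox_reference_rates("Y215F")
  optics <- lox_optics()
  sim <- simulate_lox(rates, lox_state(E_ox = 5e-6, S = 1e-2, O2 = 0),
                      times = seq(0, 0.3, by = 1e-3))
  a530 <- absorbance_at(sim, optics, 530)
  expect_equal(a530, 1500 * sim$E_red_P, tolerance = 1e-12)
  # a variant without the charge-transfer band shows a flat 530 nm trace
  opt_h <- lox_reference_optics("Y215H")
  tset <- simulate_reduction_experiment(lox_reference_rates("Y215H"), opt_h,
                                        lox_instrument(seed = 3), 5e-6,
                                        1e-2, 1.0)
  tr530 <- Filter(function(tr) tr$wavelength == 530, tset)[[1]]
  expect_error(fit_exponentials(tr530), class = "lox_no_signal")
})

test_that("trace files round-trip exactly and reject malformed input", {
  rates <- lox_reference_rates("Y215F")
  tset <- simulate_reduction_experiment(rates, lox_optics(),
                                        lox_instrument(seed = 9), 5e-6,
                                        c(1e-3, 5e-3), 0.1)
  f <- tempfile(fileext = ".csv")
  write_traces(tset, f)
  back <- read_traces(f)
  expect_equal(length(back), length(tset))
  for (i in seq_along(tset)) {
    expect_lt(max(abs(back[[i]]$time - tset[[i]]$time)), 1e-12)
    expect_lt(max(abs(back[[i]]$absorbance - tset[[i]]$absorbance)), 1e-12)
    expect_identical(back[[i]]$wavelength, tset[[i]]$wavelength)
    expect_equal(back[[i]]$meta$lactate_M, tset[[i]]$meta$lactate_M)
  }
  unlink(f)

  # empty set: valid file with header only
  f2 <- tempfile(fileext = ".csv")
  write_traces(structure(list(), class = "lox_trace_set"), f2)
  expect_equal(length(read_traces(f2)), 0)
  unlink(f2)

  # non-monotone time column is rejected with the offending line
  f3 <- tempfile(fileext = ".csv")
  writeLines(c("# lox_traces v1", "# trace", "# wavelength_nm=455",
               "time_s,absorbance_AU", "0.001,0.5", "0.003,0.4",
               "0.002,0.3"), f3)
  err <- tryCatch(read_traces(f3), error = function(e) e)
  expect_s3_class(err, "lox_parse_error")
  expect_match(conditionMessage(err), "line 7")
  unlink(f3)
})
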