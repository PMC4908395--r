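test_that("a noiseless single exponential is recovered to numerical precision", {
  tt <- seq(1.5e-3, 0.1, by = 5e-4)
  tr <- lox_trace(tt, 0.01 + 0.06 * exp(-100 * (tt - tt[1])), 455)
  ef <- fit_exponentials(tr)
  expect_equal(ef$n_phases, 1)
  expect_rel_equal(ef$phases$rate[1], 100, 1e-6)
  expect_rel_equal(ef$baseline, 0.01, 1e-6)
})

test_that("biexponential fits of noiseless traces match the chain eigenvalues", {
  rates <- lox_reference_rates("Y215F")
  tset <- simulate_reduction_experiment(rates, lox_optics(),
                                        noiseless_instrument(), 5e-6,
                                        lactate_concs = 1e-2, t_end = 0.4)
  tr455 <- Filter(function(tr) tr$wavelength == 455, tset)[[1]]
  ef <- fit_exponentials(tr455)
  lam <- observed_decay_rates(rates, 1e-2)
  expect_equal(ef$n_phases, 2)
  expect_rel_equal(ef$phases$rate[1], lam[2], 0.01)   # reduction eigenvalue
  expect_rel_equal(ef$phases$rate[2], lam[3], 0.01)   # release eigenvalue
  # the slow phase carries roughly 10% of the amplitude under default
  # optics (a little more as observed, since dead-time truncation costs
  # the fast phase proportionally more)
  amp_share <- abs(ef$phases$amplitude[2]) / sum(abs(ef$phases$amplitude))
  expect_gt(amp_share, 0.08)
  expect_lt(amp_share, 0.17)
})

test_that("the phase-detection rule keys on slow-phase amplitude", {
  rates <- lox_rates(kd = 1.0e-3, k3 = 230, k5 = 5.3, k7 = 6e5)  # pH-9.5-like
  mk_optics <- function(eps_ep) lox_optics(
    eps455 = c(E_ox = 12500, E_ox_S = 12500, E_red_P = eps_ep, E_red = 0))
  run <- function(eps_ep) {
    tset <- simulate_reduction_experiment(rates, mk_optics(eps_ep),
                                          noiseless_instrument(), 4.5e-6,
                                          lactate_concs = 1e-2, t_end = 1.2)
    fit_exponentials(Filter(function(tr) tr$wavelength == 455, tset)[[1]])
  }
  # ~10% slow-phase amplitude: second phase detected
  ef10 <- run(1250)
  expect_equal(ef10$n_phases, 2)
  expect_rel_equal(ef10$phases$rate[2], 5.3, 0.02)
  # ~2% slow-phase amplitude: below the acceptance threshold
  ef2 <- run(250)
  expect_equal(ef2$n_phases, 1)
})

test_that("hyperbolic k_obs fits recover parameters and report identifiability", {
  s <- c(0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10) * 1e-3
  pts <- data.frame(s = s, kobs = kobs_saturation_value(s, 124, 0.28e-3))
  fit <- fit_kobs_saturation(pts)
  expect_rel_equal(fit$k_red, 124, 1e-6)
  expect_rel_equal(fit$kd, 0.28e-3, 1e-6)
  expect_true(fit$kd_reliable)

  # a constant offset (nonzero reverse rate) is picked up by the free intercept
  pts_off <- data.frame(s = s, kobs = kobs_saturation_value(s, 124, 0.28e-3) + 3)
  fit_off <- fit_kobs_saturation(pts_off, fix_origin = FALSE)
  expect_equal(fit_off$intercept, 3, tolerance = 1e-4)
  expect_rel_equal(fit_off$k_red, 124, 1e-3)

  # forcing the origin on origin-true data barely moves the estimates
  fit_free <- fit_kobs_saturation(pts, fix_origin = FALSE)
  expect_lt(abs(fit_free$k_red - fit$k_red) / fit$k_red, 0.005)
  expect_lt(abs(fit_free$kd - fit$kd) / fit$kd, 0.005)
  expect_true(fit_free$intercept_zero)

  # degenerate design: one concentration
  expect_warning(one <- fit_kobs_saturation(data.frame(s = 1e-3, kobs = 90)),
                 class = "lox_identifiability_warning")
  expect_false(one$kd_reliable)
})

test_that("linear k_obs-[O2] fits return the slope as k_ox and flag flat series", {
  o2 <- c(60, 125, 250, 500) * 1e-6
  fit <- fit_kox_linear(data.frame(o2 = o2, kobs = 1.0e5 * o2))
  expect_equal(fit$k_ox, 1.0e5, tolerance = 1e-9)
  expect_true(fit$valid)

  expect_warning(flat <- fit_kox_linear(data.frame(o2 = o2, kobs = rep(5, 4))),
                 class = "lox_invalid_series_warning")
  expect_equal(flat$k_ox, 0, tolerance = 1e-12)
  expect_false(flat$valid)

  expect_error(fit_kox_linear(data.frame(o2 = o2[1:2], kobs = c(1, 2))),
               class = "lox_design_error")
})

test_that("ODE fitting of the 530 nm trace recovers k3 and k5", {
  truth <- lox_rates(kd = 0.28e-3, k3 = 150, k5 = 17, k7 = 7e5,
                     label = "Y215F")
  optics <- lox_optics()
  tset <- simulate_reduction_experiment(truth, optics,
                                        noiseless_instrument(), 4.3e-6,
                                        lactate_concs = 1e-2, t_end = 0.4)
  tr530 <- Filter(function(tr) tr$wavelength == 530, tset)[[1]]

  init <- truth; init$k3 <- 80; init$k5 <- 40
  fit <- fit_ct_trace_ode(tr530, init, optics)
  expect_rel_equal(fit$k3, 150, 1e-3)
  expect_rel_equal(fit$k5, 17, 1e-3)

  # swapped initial guesses (k3 < k5) land on the same optimum
  init_sw <- truth; init_sw$k3 <- 17; init_sw$k5 <- 150
  fit_sw <- fit_ct_trace_ode(tr530, init_sw, optics)
  expect_rel_equal(fit_sw$k3, fit$k3, 1e-6)
  expect_rel_equal(fit_sw$k5, fit$k5, 1e-6)

  # noisy traces: recovery within 5% across seeds
  for (seed in 1:3) {
    tset_n <- simulate_reduction_experiment(
      truth, optics, lox_instrument(seed = seed), 4.3e-6, 1e-2, 0.4)
    tr_n <- Filter(function(tr) tr$wavelength == 530, tset_n)[[1]]
    fit_n <- fit_ct_trace_ode(tr_n, init, optics)
    expect_rel_equal(fit_n$k3, 150, 0.05)
    expect_rel_equal(fit_n$k5, 17, 0.05)
  }

  # flat 530 nm trace: explicit no-intermediate signal
  opt_h <- lox_reference_optics("Y215H")
  tset_h <- simulate_reduction_experiment(truth, opt_h,
                                          noiseless_instrument(), 4.3e-6,
                                          1e-2, 0.4)
  tr_flat <- Filter(function(tr) tr$wavelength == 530, tset_h)[[1]]
  expect_error(fit_ct_trace_ode(tr_flat, init, optics),
               class = "lox_no_intermediate")
})

test_that("fixing the slow rate leaves the fast rate unbiased in merged traces", {
  rates <- lox_reference_rates("Y215F")
  tset <- simulate_reduction_experiment(rates, lox_optics(),
                                        noiseless_instrument(), 5e-6,
                                        lactate_concs = 2.5e-4, t_end = 0.4)
  tr <- Filter(function(x) x$wavelength == 455, tset)[[1]]
  lam <- observed_decay_rates(rates, 2.5e-4)
  ef <- fit_exponentials(tr, fix_slow_rate = rates$k5)
  expect_equal(ef$n_phases, 2)
  expect_rel_equal(ef$phases$rate[1], lam[2], 0.01)
})
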