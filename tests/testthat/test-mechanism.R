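test_that("mass-action derivatives vanish for an empty system and conserve enzyme", {
  rates <- lox_rates(kd = 1e-3, k3 = 270, k5 = 141, k7 = 1.8e6)
  d0 <- lox_derivatives(lox_state(S = 1e-2, P = 1e-4, O2 = 250e-6), rates)
  expect_true(all(d0 == 0))

  set.seed(11)
  for (i in 1:20) {
    st <- lox_state(E_ox = runif(1, 0, 1e-5), E_ox_S = runif(1, 0, 1e-5),
                    E_red_P = runif(1, 0, 1e-5), E_red = runif(1, 0, 1e-5),
                    S = runif(1, 0, 1e-2), P = runif(1, 0, 1e-3),
                    O2 = runif(1, 0, 5e-4))
    rr <- lox_rates(k1 = runif(1, 1e6, 1e8), k2 = runif(1, 10, 1e4),
                    k3 = runif(1, 1, 500), k4 = runif(1, 0, 10),
                    k5 = runif(1, 1, 500), k6 = runif(1, 0, 1e4),
                    k7 = runif(1, 1e4, 1e7))
    d <- lox_derivatives(st, rr)
    expect_lt(abs(sum(d[c("E_ox", "E_ox_S", "E_red_P", "E_red")])),
              1e-12 * max(abs(d)))
  }
  expect_error(lox_derivatives(c(E_ox = -1e-6, E_ox_S = 0, E_red_P = 0,
                                 E_red = 0, S = 0, P = 0, O2 = 0), rates),
               class = "lox_invalid_input")
})

test_that("integrated trajectory derivative matches a finite-difference oracle", {
  rates <- lox_rates(kd = 0.28e-3, k3 = 120, k5 = 20, k7 = 7e5)
  st <- lox_state(E_ox = 5e-6, S = 2e-3, O2 = 0)
  h <- 1e-7
  tmid <- 5e-3
  sim <- simulate_lox(rates, st, times = c(0, tmid - h, tmid, tmid + h),
                      rtol = 1e-10, atol = 1e-14)
  fd <- (unlist(sim[4, -1]) - unlist(sim[2, -1])) / (2 * h)
  state_mid <- unlist(sim[3, -1])
  an <- lox_derivatives(pmax(state_mid, 0), rates)
  for (sp in c("E_ox", "E_ox_S", "E_red_P", "E_red", "S", "P")) {
    if (abs(an[[sp]]) > 1e-12)
      expect_rel_equal(fd[[sp]], an[[sp]], 1e-4)
  }
})

test_that("enzyme is conserved along trajectories to better than 1e-6", {
  for (variant in c("wild-type", "Y215F", "Y215H")) {
    rates <- lox_reference_rates(variant)
    # anaerobic reduction
    sim <- simulate_lox(rates, lox_state(E_ox = 5e-6, S = 1e-2, O2 = 0),
                        times = seq(0, 0.5, by = 1e-3))
    tot <- rowSums(sim[, c("E_ox", "E_ox_S", "E_red_P", "E_red")])
    expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
    # aerobic turnover
    sim2 <- simulate_lox(rates, lox_state(E_ox = 5e-8, S = 1e-2, O2 = 250e-6),
                         times = seq(0, 5, by = 0.1))
    tot2 <- rowSums(sim2[, c("E_ox", "E_ox_S", "E_red_P", "E_red")])
    expect_lt(max(abs(tot2 - tot2[1])) / tot2[1], 1e-6)
  }
})

test_that("apparent kcat follows the reciprocal-sum relation and its limits", {
  # published Y215H constants give the published turnover within error
  expect_equal(kcat_apparent(8.2, 26, 1.0e5, 250e-6), 5.0, tolerance = 0.02)
  # two equal steps with O2 saturating -> x/2
  expect_equal(kcat_apparent(80, 80, 1e12, 1), 40, tolerance = 1e-9)
  # monotone in each argument and bounded by the slowest step
  set.seed(21)
  for (i in 1:10) {
    p <- random_rate_set()
    base <- kcat_apparent(p$k3, p$k5, p$k7, p$o2)
    expect_lt(base, min(p$k3, p$k5, p$k7 * p$o2))
    expect_gt(kcat_apparent(p$k3 * 2, p$k5, p$k7, p$o2), base)
    expect_gt(kcat_apparent(p$k3, p$k5 * 2, p$k7, p$o2), base)
    expect_gt(kcat_apparent(p$k3, p$k5, p$k7 * 2, p$o2), base)
  }
  expect_error(kcat_apparent(-1, 10, 1e5, 250e-6), class = "lox_invalid_input")
})

test_that("apparent kcat agrees with a long ODE turnover simulation", {
  rates <- lox_reference_rates("wild-type")
  v <- cycle_steady_state_rate(rates, s = 0.1, o2 = 250e-6)
  expect_rel_equal(v, kcat_apparent(270, 141, 1.8e6, 250e-6), 0.01)
  # and the ODE trace itself reproduces the analytic cycle rate
  e0 <- 5e-8
  sim <- simulate_lox(rates, lox_state(E_ox = e0, S = 0.1, O2 = 250e-6),
                      times = seq(0, 2, by = 0.05))
  slope <- coef(lm(P ~ time, data = sim[sim$time >= 0.5, ]))[["time"]]
  expect_rel_equal(slope / e0, v, 0.01)
})

test_that("solving for k5 inverts the kcat relation and flags infeasibility", {
  expect_equal(round(solve_k5_from_kcat(5.0, 8.2, 1.0e5, 250e-6)), 26)
  set.seed(31)
  for (i in 1:10) {
    p <- random_rate_set()
    kc <- kcat_apparent(p$k3, p$k5, p$k7, p$o2)
    expect_rel_equal(solve_k5_from_kcat(kc, p$k3, p$k7, p$o2), p$k5, 1e-9)
  }
  expect_error(solve_k5_from_kcat(10, 8.2, 1e5, 250e-6),
               class = "lox_infeasible")
  # recover k5 from a simulated turnover rate with known constants; deep
  # substrate saturation so the binding step contributes nothing
  rates <- lox_reference_rates("Y215H")
  tab <- simulate_initial_rate_table(rates, lactate_concs = 0.5,
                                     replicates = 1, noise_cv = 0)
  k5_rec <- solve_k5_from_kcat(tab$v_over_e0_per_s, 8.2, 1e5, 250e-6)
  expect_rel_equal(k5_rec, 26, 0.01)
})

test_that("O2-saturated kcat and Km(O2) reproduce the published trio", {
  km_uM <- function(k3, k5, k7) 1e6 * km_oxygen(kcat_saturating(k3, k5), k7)
  expect_equal(km_uM(270, 141, 1.8e6), 51, tolerance = 1)
  expect_equal(km_uM(120, 20, 7.0e5), 24, tolerance = 1)
  expect_equal(km_uM(8.2, 26, 1.0e5), 62, tolerance = 1)
  expect_equal(kcat_saturating(80, 80), 40)
})

test_that("rate-limitation fractions sum to one and match published percentages", {
  cases <- list(c(230, 5.3, 162, 95), c(120, 20, 175, 78),
                c(270, 141, 450, 54), c(170, 57, 275, 65))
  for (cs in cases) {
    fr <- rate_limitation_fractions(cs[1], cs[2], cs[3] / 250e-6, 250e-6)
    expect_equal(sum(fr), 1, tolerance = 1e-9)
    expect_equal(round(100 * fr[["k5"]]), cs[4])
  }
  fr3 <- rate_limitation_fractions(50, 50, 50 / 250e-6, 250e-6)
  expect_equal(unname(fr3), rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("kcat_apparent is exactly hyperbolic in O2 with the derived Km", {
  set.seed(41)
  for (i in 1:10) {
    p <- random_rate_set()
    ks <- kcat_saturating(p$k3, p$k5)
    km <- km_oxygen(ks, p$k7)
    expect_equal(kcat_apparent(p$k3, p$k5, p$k7, p$o2),
                 ks * p$o2 / (km + p$o2), tolerance = 1e-12)
  }
})

test_that("hyperbolic k_obs value behaves at the origin, half-saturation and asymptote", {
  expect_identical(kobs_saturation_value(0, 124, 0.28e-3), 0)
  expect_equal(kobs_saturation_value(0.28e-3, 124, 0.28e-3), 62)
  expect_rel_equal(kobs_saturation_value(100 * 0.28e-3, 124, 0.28e-3), 124,
                   0.01)
  expect_error(kobs_saturation_value(-1e-3, 124, 0.28e-3),
               class = "lox_invalid_input")
})

test_that("analytic decay rates expose the linear-chain structure", {
  rates <- lox_reference_rates("Y215F")
  lam <- observed_decay_rates(rates, s = 1e-2)
  expect_equal(length(lam), 4)
  expect_true(all(diff(lam) <= 0))
  expect_equal(lam[4], 0)
  # with k4 = 0 the release step decouples: one eigenvalue is exactly k5
  expect_equal(lam[3], rates$k5, tolerance = 1e-9)
  # the reduction eigenvalue matches the analytic 2x2 binding/reduction block
  a <- rates$k1 * 1e-2; b <- rates$k2 + rates$k3
  lam_red <- ((a + b) - sqrt((a + b)^2 - 4 * rates$k1 * 1e-2 * rates$k3)) / 2
  expect_rel_equal(lam[2], lam_red, 1e-9)
  # a blocked chain (k3 = 0) stalls: only binding relaxes
  blocked <- lox_rates(kd = 0.28e-3, k3 = 0, k5 = 20, k7 = 7e5)
  lam_b <- observed_decay_rates(blocked, s = 1e-2)
  expect_equal(sum(lam_b == 0), 2)
})

test_that("rate constants serialize to annotated key-value documents and back", {
  rates <- lox_rates(kd = 0.28e-3, k3 = 120, k5 = 20, k7 = 7e5,
                     label = "Y215F", ph = 6.5)
  for (ext in c(".json", ".yaml")) {
    f <- tempfile(fileext = ext)
    write_lox_rates(rates, f)
    back <- read_lox_rates(f)
    for (k in c("k1", "k2", "k3", "k4", "k5", "k6", "k7"))
      expect_equal(back[[k]], rates[[k]], tolerance = 1e-12)
    expect_identical(back$label, "Y215F")
    unlink(f)
  }
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(k1_per_M_per_s = 1, bogus = 2), f,
                       auto_unbox = TRUE)
  expect_error(read_lox_rates(f), class = "lox_parse_error")
  unlink(f)
})
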