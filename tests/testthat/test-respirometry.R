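make_cycle_trace <- function(po2_fun, cycle_min = 6, closed_min = 3,
                             n_cycles = 1, dt = 1 / 60) {
  t <- seq(0, n_cycles * cycle_min - dt, by = dt)
  phase <- ifelse(t %% cycle_min < cycle_min - closed_min, "flush", "closed")
  o2_trace(t, po2_fun(t), phase, as.integer(t %/% cycle_min) + 1L)
}

test_that("cycle slope fitting recovers exact lines and flags degenerates", {
  tr <- make_cycle_trace(function(t) 150 - 1.0 * t)
  regs <- fit_cycle_slopes(tr)
  expect_equal(regs$slope, -1.0, tolerance = 1e-10)
  expect_equal(regs$r_squared, 1, tolerance = 1e-12)
  expect_true(regs$retained)
  # constant PO2: zero-variance response, flagged not retained
  tr2 <- make_cycle_trace(function(t) rep(100, length(t)))
  regs2 <- fit_cycle_slopes(tr2)
  expect_equal(regs2$slope, 0)
  expect_false(regs2$retained)
  expect_equal(regs2$flag, "constant_po2")
})

test_that("fitted slopes match a closed-form OLS oracle", {
  set.seed(7)
  tr <- make_cycle_trace(function(t) 150 - 2.3 * t +
                           rnorm(length(t), 0, 0.3))
  regs <- fit_cycle_slopes(tr, window_min = 2)
  closed <- tr[tr$phase == "closed", ]
  win <- closed[closed$time_min >= max(closed$time_min) - 2, ]
  sxy <- sum((win$time_min - mean(win$time_min)) *
               (win$po2_mmHg - mean(win$po2_mmHg)))
  sxx <- sum((win$time_min - mean(win$time_min))^2)
  expect_equal(regs$slope, sxy / sxx, tolerance = 1e-10)
})

test_that("the R2 filter retains clean cycles and drops corrupted ones", {
  set.seed(21)
  tr <- make_cycle_trace(function(t) 150 - 2 * t %% 6,
                         n_cycles = 5)
  tr$po2_mmHg <- tr$po2_mmHg + rnorm(nrow(tr), 0, 0.05)
  # corrupt cycle 3's closed window with gross non-linear noise
  bad <- tr$cycle == 3 & tr$phase == "closed"
  tr$po2_mmHg[bad] <- tr$po2_mmHg[bad] + rnorm(sum(bad), 0, 5)
  regs <- fit_cycle_slopes(tr)
  expect_true(all(regs$retained[regs$cycle != 3]))
  expect_false(regs$retained[regs$cycle == 3])
})

test_that("the chamber equation is applied exactly and is linear", {
  setup <- std_setup(0.1, 2)
  alpha <- o2_solubility(setup$conditions)
  expect_equal(mo2_from_slope(-1, setup), 1 * alpha * 1.9 / 0.1)
  expect_equal(mo2_from_slope(0, setup), 0)
  # linear in slope
  expect_equal(mo2_from_slope(-3, setup), 3 * mo2_from_slope(-1, setup))
  # linear in effective volume; vanishing as V -> M_f
  near <- chamber_setup(0.1 + 1e-9, 0.1, setup$conditions)
  expect_lt(mo2_from_slope(-1, near), 1e-6)
  wide <- chamber_setup(3.9, 0.1, setup$conditions)
  expect_equal(mo2_from_slope(-1, wide) / mo2_from_slope(-1, setup),
               3.8 / 1.9)
})

test_that("background correction interpolates linearly in time", {
  regs <- data.frame(cycle = 1:3, slope = -1, intercept = 150,
                     r_squared = 1, n_points = 10,
                     window_start = c(0, 10, 20), window_end = c(2, 12, 22),
                     mean_po2 = 140, retained = TRUE, flag = "")
  ser <- mo2_series(regs, std_setup())
  same <- background_correct(ser, 0, 0, 0, 22)
  expect_equal(same$mo2, ser$mo2)
  expect_true(all(same$background_corrected))
  # pre 0, post 2: the middle record (t = 11) sits at exactly half the ramp
  corr <- background_correct(ser, 0, 2, 1, 21)
  expect_equal(ser$mo2[2] - corr$mo2[2], 1)
})

test_that("background-corrected SMR recovers truth where uncorrected is biased", {
  wc <- std_conditions()
  fish <- fish_model(std_smr_umol(), 20, 0.091)
  bg <- c(1, 2)  # umol/min chamber-level, ramping over the trace
  cfg <- trace_sim_config(2.5, duration_h = 4, noise_sd = 0,
                          background_rate_start = bg[1],
                          background_rate_end = bg[2],
                          conditions = wc, seed = 3)
  tr <- simulate_trace(fish, cfg)
  ser <- mo2_series(fit_cycle_slopes(tr), std_setup())
  raw_smr <- estimate_smr(ser)$value
  corr <- background_correct(ser, bg[1] / fish$mass_kg,
                             bg[2] / fish$mass_kg, 0, 4 * 60)
  corr_smr <- estimate_smr(corr)$value
  expect_equal(corr_smr, fish$smr_true, tolerance = 0.01)
  # uncorrected estimate is biased high by roughly the mean background
  expect_gt(raw_smr, fish$smr_true * 1.05)
})

test_that("SMR is the mean of the lowest decile with a ceiling count", {
  regs <- data.frame(cycle = 1:20, slope = -(1:20), intercept = 150,
                     r_squared = 1, n_points = 10,
                     window_start = seq(0, 114, 6), window_end = seq(2, 116, 6),
                     mean_po2 = 140, retained = TRUE, flag = "")
  setup <- std_setup()
  ser <- mo2_series(regs, setup)
  unit <- mo2_from_slope(-1, setup)
  est <- estimate_smr(ser)
  expect_equal(est$value, 1.5 * unit)  # mean of the two lowest of 1..20
  expect_equal(est$n_used, 2L)
  # permutation invariance
  ser_shuf <- ser[sample(nrow(ser)), ]
  class(ser_shuf) <- class(ser)
  expect_equal(estimate_smr(ser_shuf)$value, est$value)
  # all-equal records give that constant
  ser$mo2 <- rep(3.3, 20)
  expect_equal(estimate_smr(ser)$value, 3.3)
  expect_error(estimate_smr(ser[1:5, ]), ">= 10 retained")
})

test_that("zero-noise full-chain recovery hits (smr_true, pcrit_true)", {
  wc <- std_conditions()
  fish <- fish_model(std_smr_umol(), 36.2, 0.091)
  setup <- std_setup()
  cfg <- trace_sim_config(2.5, duration_h = 3, noise_sd = 0,
                          conditions = wc, seed = 1)
  tr <- simulate_trace(fish, cfg)
  ser <- mo2_series(fit_cycle_slopes(tr), setup)
  smr <- estimate_smr(ser)
  expect_equal(smr$value, fish$smr_true, tolerance = 1e-6)
  rcfg <- trace_sim_config(2.5, duration_h = 12, noise_sd = 0,
                           conditions = wc, seed = 2)
  run <- simulate_closed_pcrit_run(fish, rcfg, 12.7)
  pc <- estimate_pcrit(run, smr, setup)
  bin_width_po2 <- 2 * abs(fish$smr_true * fish$mass_kg /
                             (o2_solubility(wc) * (2.5 - fish$mass_kg)))
  expect_false(pc$censored)
  expect_lt(abs(pc$value - 36.2), bin_width_po2)
  expect_lt(abs(pc$value_first_below - 36.2), bin_width_po2)
})

test_that("a fish that never conforms yields a censored Pcrit", {
  wc <- std_conditions()
  fish <- fish_model(std_smr_umol(), 15, 0.091)  # breakpoint below stop PO2
  cfg <- trace_sim_config(2.5, duration_h = 12, noise_sd = 0,
                          conditions = wc, seed = 4)
  run <- simulate_closed_pcrit_run(fish, cfg, 40)
  pc <- estimate_pcrit(run, smr_estimate(fish$smr_true), std_setup())
  expect_true(pc$censored)
  expect_equal(pc$value, min(run$po2_mmHg))
})

test_that("a pure conformer crosses SMR at the predicted tension", {
  # MO2 proportional to PO2 from the start; SMR set to k * P* crosses at P*
  wc <- std_conditions()
  fish <- fish_model(std_smr_umol(), 200, 0.091)  # conformer everywhere
  cfg <- trace_sim_config(2.5, duration_h = 12, noise_sd = 0,
                          ambient_po2 = 150, conditions = wc, seed = 5)
  run <- suppressWarnings(simulate_closed_pcrit_run(fish, cfg, 12.7))
  p_star <- 60
  smr_at_pstar <- smr_estimate(fish$smr_true * p_star / fish$pcrit_true)
  pc <- estimate_pcrit(run, smr_at_pstar, std_setup())
  bin_width_po2 <- 2 * fish$smr_true * (p_star / fish$pcrit_true) *
    fish$mass_kg / (o2_solubility(wc) * (2.5 - 0.091))
  expect_lt(abs(pc$value - p_star), bin_width_po2)
})

test_that("Pcrit error stays small under measurement noise", {
  wc <- std_conditions()
  setup <- std_setup()
  fish <- fish_model(std_smr_umol(), 36.2, 0.091)
  smr <- smr_estimate(fish$smr_true)
  errs <- vapply(1:100, function(i) {
    cfg <- trace_sim_config(2.5, duration_h = 12, noise_sd = 0.5,
                            conditions = wc, seed = 20000 + i)
    run <- simulate_closed_pcrit_run(fish, cfg, 12.7)
    abs(estimate_pcrit(run, smr, setup)$value - 36.2)
  }, numeric(1))
  expect_lte(median(errs), 3)
})
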