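test_that("gas percent to PO2 conversion handles dry and humidified gas", {
  wc <- water_conditions(22, 0)
  expect_equal(percent_o2_to_po2(0, wc), 0)
  expect_equal(percent_o2_to_po2(100, wc, humidified = FALSE), 760)
  # hand arithmetic with the Weiss-Price vapor pressure at 22 degC
  vp <- 760 * exp(24.4543 - 67.4509 * (100 / 295.15) -
                    4.8489 * log(295.15 / 100))
  expect_equal(percent_o2_to_po2(21, wc, humidified = TRUE),
               0.21 * (760 - vp), tolerance = 1e-10)
  expect_error(percent_o2_to_po2(101, wc), "0, 100")
})

test_that("saturation normalization anchors the endpoints and round-trips", {
  po2 <- c(0, 5, 10, 20, 40, 148)
  a0 <- 0.15; a100 <- 0.85
  s_true <- c(0, po2[2:5]^2 / (15^2 + po2[2:5]^2), 1)
  cv <- oec_curve(c(0, 1, 2, 5, 10, 100), po2,
                  a0 + (a100 - a0) * s_true, ph = 7.4)
  sat <- saturation_from_absorbance(cv)
  expect_equal(sat$saturation, s_true[2:5], tolerance = 1e-12)
  expect_false(any(sat$out_of_range))
  # simulated plate round trip at zero noise
  wc <- water_conditions(22, 35)
  pl <- simulate_oec_plate(20, 1.8, -0.45, ph_levels = 7.4, noise_sd = 0,
                           conditions = wc)
  sat <- saturation_from_absorbance(pl[[1]])
  s_gen <- sat$po2_mmHg^1.8 / (20^1.8 + sat$po2_mmHg^1.8)
  expect_equal(sat$saturation, s_gen, tolerance = 1e-12)
  # coincident endpoints carry no dynamic range
  flat <- oec_curve(c(0, 50, 100), c(0, 70, 140), c(0.5, 0.5, 0.5), 7.4)
  expect_error(saturation_from_absorbance(flat), "dynamic range")
})

test_that("Hill fit arithmetic: slope 2, intercept -2 gives P50 = 10", {
  po2 <- c(3, 5, 8, 10, 12, 20, 30)
  y <- 2 * log10(po2) - 2           # exact Hill line
  s <- 1 / (1 + 10^(-y))
  fit <- fit_hill(data.frame(po2_mmHg = po2, saturation = s),
                  window = c(0.01, 0.99))
  expect_equal(fit$n_h, 2, tolerance = 1e-9)
  expect_equal(fit$intercept, -2, tolerance = 1e-9)
  expect_equal(fit$p50, 10, tolerance = 1e-9)
  # at PO2 = P50 the fitted line predicts log-odds 0 (S = 0.5)
  expect_equal(fit$intercept + fit$n_h * log10(fit$p50), 0,
               tolerance = 1e-9)
})

test_that("Hill fit recovers an exact model and rejects sparse windows", {
  sat <- hill_sat(20, 2.5)
  fit <- fit_hill(sat)
  expect_equal(fit$n_h, 2.5, tolerance = 1e-6)
  expect_equal(fit$p50, 20, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_error(fit_hill(sat[sat$saturation < 0.25, ]), ">= 3 points")
})

test_that("Hill fit is invariant to affine absorbance rescaling", {
  wc <- water_conditions(22, 35)
  pl <- simulate_oec_plate(18, 1.6, 0, ph_levels = 7.4, noise_sd = 0.005,
                           conditions = wc, seed = 8)
  cv <- pl[[1]]
  fit1 <- fit_hill(saturation_from_absorbance(cv))
  cv2 <- cv
  cv2$absorbance <- 3.7 * cv$absorbance - 0.42   # gain and offset
  attr(cv2, "ph") <- attr(cv, "ph")
  fit2 <- fit_hill(saturation_from_absorbance(cv2))
  expect_equal(fit2$p50, fit1$p50, tolerance = 1e-12)
  expect_equal(fit2$n_h, fit1$n_h, tolerance = 1e-12)
})

test_that("P50 recovery is invariant to the gas step set", {
  steps_a <- c(0, 0.5, 1, 1.5, 2, 3, 5, 8, 12, 21, 100)
  steps_b <- c(0, 0.7, 1.2, 1.8, 2.5, 4, 6, 10, 15, 100)
  wc <- water_conditions(22, 35)
  fits <- lapply(list(steps_a, steps_b), function(st) {
    pl <- simulate_oec_plate(15, 1.8, 0, ph_levels = 7.4,
                             o2_steps_percent = st, noise_sd = 0,
                             conditions = wc)
    fit_hill(saturation_from_absorbance(pl[[1]]))
  })
  expect_equal(fits[[1]]$p50, 15, tolerance = 1e-6)
  expect_equal(fits[[2]]$p50, 15, tolerance = 1e-6)
})

test_that("raising in-window saturation lowers the fitted P50", {
  sat <- hill_sat(20, 2)
  fit0 <- fit_hill(sat)
  sat_up <- sat
  win <- sat$saturation > 0.2 & sat$saturation < 0.8
  sat_up$saturation[win] <- sat$saturation[win] +
    0.05 * (1 - sat$saturation[win])
  expect_lt(fit_hill(sat_up)$p50, fit0$p50)
})

test_that("P50 recovery tolerates absorbance noise of 1% of range", {
  wc <- water_conditions(22, 35)
  est <- vapply(1:100, function(i) {
    pl <- simulate_oec_plate(20, 1.8, 0, ph_levels = 7.4,
                             a_deoxy = 0.1, a_oxy = 0.9,
                             noise_sd = 0.008, conditions = wc,
                             seed = 3000 + i)
    fit_hill(saturation_from_absorbance(pl[[1]]),
             window = c(0.1, 0.9))$p50
  }, numeric(1))
  # average recovery accuracy on the sparse 15-step assay grid
  expect_lt(mean(abs(est - 20) / 20), 0.05)
  expect_lt(abs(mean(est) - 20) / 20, 0.02)
})

test_that("Bohr coefficients: pairwise arithmetic and OLS recovery", {
  b <- bohr_coefficient(c(7.4, 7.8), c(20, 10))
  expect_equal(b$phi, (log10(10) - log10(20)) / 0.4, tolerance = 1e-12)
  expect_equal(round(b$phi, 4), -0.7526)
  expect_equal(bohr_coefficient(c(7, 7.4, 7.8), c(15, 15, 15))$phi, 0)
  # three-pH exact model
  ph <- c(7, 7.4, 7.8)
  p50 <- 10^(log10(22) - 0.6 * (ph - 7.4))
  b3 <- bohr_coefficient(ph, p50)
  expect_equal(b3$phi, -0.6, tolerance = 1e-9)
  expect_equal(nrow(b3$pairwise), 3)
  expect_equal(b3$pairwise$phi, rep(-0.6, 3), tolerance = 1e-9)
  expect_error(bohr_coefficient(c(7.4, 7.4), c(20, 21)), "distinct pH")
})
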