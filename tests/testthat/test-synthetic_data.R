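test_that("trace simulation is bit-reproducible under a fixed seed", {
  fish <- fish_model(std_smr_umol(), 36.2, 0.091,
                     activity_rate = 6, activity_magnitude = 0.5)
  cfg <- trace_sim_config(2.5, duration_h = 1, noise_sd = 0.3,
                          conditions = std_conditions(), seed = 42)
  expect_identical(simulate_trace(fish, cfg), simulate_trace(fish, cfg))
  run <- trace_sim_config(2.5, duration_h = 6, noise_sd = 0.3,
                          conditions = std_conditions(), seed = 43)
  expect_identical(simulate_closed_pcrit_run(fish, run, 20),
                   simulate_closed_pcrit_run(fish, run, 20))
})

test_that("zero-noise closed phases decline linearly at the chamber-equation slope", {
  wc <- std_conditions()
  fish <- fish_model(std_smr_umol(), 10, 0.091)  # pcrit far below ambient
  cfg <- trace_sim_config(2.5, duration_h = 0.5, noise_sd = 0,
                          conditions = wc, seed = 1)
  tr <- simulate_trace(fish, cfg)
  expected_slope <- -fish$smr_true * fish$mass_kg /
    (o2_solubility(wc) * (2.5 - fish$mass_kg))
  closed <- tr[tr$phase == "closed" & tr$cycle == 2, ]
  slopes <- diff(closed$po2_mmHg) / diff(closed$time_min)
  expect_equal(slopes, rep(expected_slope, length(slopes)),
               tolerance = 1e-9)
})

test_that("below pcrit the zero-noise decline matches the analytic exponential", {
  wc <- std_conditions()
  fish <- fish_model(std_smr_umol(), 100, 0.091)  # conformer from the start
  cfg <- trace_sim_config(2.5, duration_h = 2, noise_sd = 0,
                          ambient_po2 = 80, conditions = wc, seed = 1)
  run <- suppressWarnings(simulate_closed_pcrit_run(fish, cfg, 5))
  k <- fish$smr_true * fish$mass_kg /
    (fish$pcrit_true * o2_solubility(wc) * (2.5 - fish$mass_kg))
  analytic <- 80 * exp(-k * run$time_min)
  expect_equal(run$po2_mmHg, analytic, tolerance = 1e-3)
})

test_that("oxygen is conserved over every closed phase", {
  fish <- fish_model(std_smr_umol(), 36.2, 0.091,
                     activity_rate = 10, activity_magnitude = 1)
  cfg <- trace_sim_config(2.5, duration_h = 2, noise_sd = 0,
                          background_rate_start = 0.5,
                          background_rate_end = 1.5,
                          conditions = std_conditions(), seed = 5)
  tr <- simulate_trace(fish, cfg)
  bud <- attr(tr, "o2_budget")
  expect_gt(nrow(bud), 10)
  expect_equal(bud$po2_drop_umol, bud$o2_removed_umol, tolerance = 1e-6)
})

test_that("pcrit-run preconditions and clipping flags are enforced", {
  fish <- fish_model(std_smr_umol(), 36.2, 0.091)
  cfg <- trace_sim_config(2.5, duration_h = 1, conditions = std_conditions())
  expect_error(simulate_closed_pcrit_run(fish, cfg, 150), "below ambient")
  expect_error(simulate_closed_pcrit_run(fish, cfg, 200), "below ambient")
})

test_that("simulated oxygen-equilibrium plates follow the Bohr-Hill model", {
  wc <- water_conditions(22, 35)
  # pick the p50 to sit exactly on a gas step: absorbance lands midway
  p50 <- percent_o2_to_po2(2, wc)
  pl <- simulate_oec_plate(p50, 2, 0, ph_levels = 7.4, a_deoxy = 0.2,
                           a_oxy = 0.8, noise_sd = 0, conditions = wc)
  cv <- pl[[1]]
  expect_equal(cv$absorbance[cv$gas_percent_o2 == 2], 0.5)
  # zero Bohr coefficient: identical curves at every pH
  pl0 <- simulate_oec_plate(20, 1.8, 0, noise_sd = 0, conditions = wc)
  expect_equal(pl0[[1]]$absorbance, pl0[[2]]$absorbance)
  expect_equal(pl0[[1]]$absorbance, pl0[[3]]$absorbance)
  # Bohr arithmetic: phi = -0.75 moves P50 from 20 to 10.02 over 0.4 pH
  plb <- simulate_oec_plate(20, 1.8, -0.75, ph_levels = c(7.4, 7.8),
                            noise_sd = 0, conditions = wc)
  f78 <- fit_hill(saturation_from_absorbance(plb[[2]]),
                  window = c(0.05, 0.95))
  expect_equal(f78$p50, 20 * 10^(-0.75 * 0.4), tolerance = 1e-6)
  expect_equal(round(f78$p50, 2), 10.02)
})

test_that("ct generation encodes abundance and efficiency as specified", {
  # equal abundance, equal efficiency: equal ct
  tab <- simulate_ct_table(c(ef1a = 1, g1 = 0.5, g2 = 0.5),
                           c(ef1a = 2, g1 = 1.9, g2 = 1.9), n_samples = 2)
  s1 <- tab[tab$sample_id == "normoxia_1", ]
  expect_equal(s1$ct[s1$gene == "g1"], s1$ct[s1$gene == "g2"])
  # 64-fold abundance ratio at E = 2 is exactly 6 cycles
  tab <- simulate_ct_table(c(ef1a = 1, hi = 1, lo = 1 / 64),
                           c(ef1a = 2, hi = 2, lo = 2), n_samples = 1)
  s1 <- tab[tab$sample_id == "normoxia_1", ]
  expect_equal(s1$ct[s1$gene == "lo"] - s1$ct[s1$gene == "hi"], 6)
  expect_error(
    simulate_ct_table(c(ef1a = 1, g = 1), c(ef1a = 2, g = 1), n_samples = 1),
    "1, 2")
})

test_that("zero-noise ct tables are exactly inverted by the abundance estimator", {
  ab <- c(ef1a = 1, anchor = 1, g1 = 0.37, g2 = 0.019)
  ef <- c(ef1a = 1.92, anchor = 1.88, g1 = 1.80, g2 = 1.96)
  tab <- simulate_ct_table(ab, ef, n_samples = 3, loading_sd = 0.2,
                           seed = 11)
  ra <- relative_abundance(tab, "anchor", genes = c("g1", "g2"))
  expect_equal(ra$per_sample$abundance[ra$per_sample$gene == "g1"],
               rep(0.37, 6), tolerance = 1e-12)
  expect_equal(ra$per_sample$abundance[ra$per_sample$gene == "g2"],
               rep(0.019, 6), tolerance = 1e-12)
})

test_that("morphometry generator is exact at zero variance and unbiased under noise", {
  m <- simulate_morphometry(348.9, 91)
  expect_equal(gill_area(m)$mass_specific_area_mm2_g, 348.9)
  # doubling mass at fixed total area halves the mass-specific area
  a1 <- gill_area(simulate_morphometry(300, 50))$total_area_mm2
  m2 <- simulate_morphometry(300, 50)
  m2$body_mass_g <- 100
  expect_equal(gill_area(m2)$mass_specific_area_mm2_g,
               a1 / 100)
  # Monte-Carlo: spacing noise leaves the estimator within 2% in expectation
  set.seed(99)
  est <- vapply(1:200, function(i)
    gill_area(simulate_morphometry(348.9, 91, spacing_cv = 0.1,
                                   seed = 1000 + i))$mass_specific_area_mm2_g,
    numeric(1))
  expect_lt(abs(mean(est) - 348.9) / 348.9, 0.02)
})
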