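#' Study configuration for the desk-scale acclimation experiment
#'
#' Assembles every stage's parameters for [run_study()]: a two-treatment
#' (normoxia/hypoxia) acclimation experiment with `n_per_group` fish per
#' treatment, whole-animal respirometry before and after acclimation,
#' hemolysate oxygen-equilibrium plates at three pH levels, hemoglobin
#' subunit qPCR and gill morphometrics. The defaults are calibrated to the
#' red drum acclimation study the package models: 91 g fish at 22 degC /
#' 35 psu (respirometry at 24 degC), SMR near 151-167 mgO2 kg^-1 h^-1,
#' a hypoxia-treatment Pcrit falling from 36.2 to 28.1 mmHg, hemolysate pH
#' levels 7/7.4/7.8, primer efficiencies in the 77-96% band, and a gill
#' area near 349 mm^2 g^-1.
#'
#' @param n_per_group Fish per treatment (default 7).
#' @param mass_mean_g,mass_sd_g Body-mass distribution (default 91 +/- 5 g).
#' @param smr_mg_kg_h Named list of group-mean SMR (mgO2 kg^-1 h^-1) with
#'   entries `normoxia_pre`, `normoxia_post`, `hypoxia_pre`, `hypoxia_post`.
#' @param pcrit_mmHg Same structure, true critical tensions in mmHg.
#' @param individual_cv Lognormal between-fish CV applied to SMR, Pcrit,
#'   P50 and Bohr truths (default 0.06).
#' @param chamber_volume_L Respirometer volume (default 2.5 L).
#' @param smr_duration_h SMR trace length per fish (default 6 h at desk
#'   scale; the protocol the defaults emulate ran >= 20 h).
#' @param trace_noise_sd PO2 measurement noise, mmHg (default 0.2).
#' @param activity_rate,activity_magnitude Spontaneous activity model
#'   (default 6 bursts/h of +50% SMR).
#' @param ambient_po2,stop_po2 Pcrit-run bounds, mmHg (defaults 150, 12.7).
#' @param p50_ph74 Named vector of group-mean P50 at pH 7.4
#'   (`normoxia`, `hypoxia`), mmHg.
#' @param hill_n,bohr_phi Hill coefficient and Bohr coefficient truths.
#' @param oec_noise_sd Absorbance noise (default 0.008).
#' @param hb_abundances,hb_efficiencies Named vectors for the Ct-table
#'   generator (defaults: ef1a reference, Hba-3.1 anchor at 1, Hba-3.2 at
#'   0.12, minor subunits below; efficiencies 1.77-1.96).
#' @param hb_fold_changes Named vector of hypoxia fold changes (defaults:
#'   up-regulation of Hba-2, Hba-3.2 and Hbb-3.1).
#' @param ct_noise_sd,loading_sd Ct noise (cycles) and per-sample loading
#'   spread (default 0.2 and 0.05).
#' @param gill_area_mm2_g,diffusion_um Named vectors (`normoxia`,
#'   `hypoxia`) of morphometric truths.
#' @param morph_cv Measurement CV for spacing and diffusion (default 0.1).
#' @param temperature_C,salinity_psu Water conditions (defaults 24, 35 for
#'   respirometry).
#' @param seed Base integer seed; every stage derives its own sub-seed from
#'   it, so a run is fully reproducible.
#' @return An object of class `study_config`.
#' @export
study_config <- function(
    n_per_group = 7, mass_mean_g = 91, mass_sd_g = 5,
    smr_mg_kg_h = list(normoxia_pre = 151, normoxia_post = 162,
                       hypoxia_pre = 167, hypoxia_post = 166),
    pcrit_mmHg = list(normoxia_pre = 36.2, normoxia_post = 36.2,
                      hypoxia_pre = 36.2, hypoxia_post = 28.1),
    individual_cv = 0.06,
    chamber_volume_L = 2.5, smr_duration_h = 6, trace_noise_sd = 0.2,
    activity_rate = 6, activity_magnitude = 0.5,
    ambient_po2 = 150, stop_po2 = 12.7,
    p50_ph74 = c(normoxia = 22, hypoxia = 19),
    hill_n = 1.8, bohr_phi = -0.45, oec_noise_sd = 0.008,
    hb_abundances = c(ef1a = 1, hba_3.1 = 1, hba_3.2 = 0.12,
                      hba_2 = 0.04, hba_6.1 = 0.02, hba_short = 0.01,
                      hbb_3.1 = 1),
    hb_efficiencies = c(ef1a = 1.92, hba_3.1 = 1.88, hba_3.2 = 1.80,
                        hba_2 = 1.96, hba_6.1 = 1.77, hba_short = 1.85,
                        hbb_3.1 = 1.90),
    hb_fold_changes = c(hba_2 = 4, hba_3.2 = 4, hbb_3.1 = 2.5),
    ct_noise_sd = 0.2, loading_sd = 0.05,
    gill_area_mm2_g = c(normoxia = 348.9, hypoxia = 369.9),
    diffusion_um = c(normoxia = 1.22, hypoxia = 1.18),
    morph_cv = 0.1,
    temperature_C = 24, salinity_psu = 35,
    seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_per_group >= 2, all(unlist(smr_mg_kg_h) > 0),
            all(unlist(pcrit_mmHg) > 0), individual_cv >= 0,
            chamber_volume_L > 0, smr_duration_h > 0)
  class(cfg) <- "study_config"
  cfg
}

# Deterministic sub-seed derivation, kept inside 32-bit integer range.
.sub_seed <- function(base, stage, i = 0L) {
  as.integer((as.numeric(base) + stage * 10007 + i * 101) %%
               .Machine$integer.max)
}

# Per-fish truths: group-level mean with lognormal individual variation.
.individual <- function(mean_value, cv, seed) {
  with_seed(seed, mean_value * exp(stats::rnorm(1, 0, cv)))
}

# SMR + Pcrit protocol for one fish at one phase (pre/post acclimation).
.fish_respirometry <- function(smr_true_umol, pcrit_true, mass_kg, cfg,
                               seed) {
  conditions <- water_conditions(cfg$temperature_C, cfg$salinity_psu)
  setup <- chamber_setup(cfg$chamber_volume_L, mass_kg, conditions)
  fish <- fish_model(smr_true_umol, pcrit_true, mass_kg,
                     activity_rate = cfg$activity_rate,
                     activity_magnitude = cfg$activity_magnitude)
  tr_cfg <- trace_sim_config(cfg$chamber_volume_L,
                             duration_h = cfg$smr_duration_h,
                             ambient_po2 = cfg$ambient_po2,
                             noise_sd = cfg$trace_noise_sd,
                             conditions = conditions, seed = seed)
  trace <- simulate_trace(fish, tr_cfg)
  series <- mo2_series(fit_cycle_slopes(trace), setup)
  smr <- estimate_smr(series)
  quiet_fish <- fish_model(smr_true_umol, pcrit_true, mass_kg)
  run_cfg <- trace_sim_config(cfg$chamber_volume_L, duration_h = 12,
                              ambient_po2 = cfg$ambient_po2,
                              noise_sd = cfg$trace_noise_sd,
                              conditions = conditions,
                              seed = .sub_seed(seed, 7L))
  run <- suppressWarnings(
    simulate_closed_pcrit_run(quiet_fish, run_cfg, cfg$stop_po2))
  pcrit <- estimate_pcrit(run, smr, setup)
  list(smr_mg_kg_h = mo2_unit_convert(smr$value, "umol_kg_min", "mg_kg_h"),
       pcrit_mmHg = pcrit$value,
       pcrit_first_below = pcrit$value_first_below,
       censored = pcrit$censored)
}

#' Run the full desk-scale acclimation study
#'
#' Simulates and analyses the whole experiment defined by a
#' [study_config()]: per-fish SMR and Pcrit before and after acclimation
#' (paired one-tailed t on Pcrit, paired two-tailed t on SMR), hemolysate
#' P50 at three pH levels (two-way treatment x pH ANOVA, Bohr coefficients,
#' unpaired t), hemoglobin-subunit expression (efficiency-corrected fold
#' changes with unpaired t per gene, anchored relative abundance) and gill
#' morphometrics (unpaired t on mass-specific area and diffusion distance).
#' Deterministic for a fixed `config$seed`.
#'
#' @param config A [study_config()].
#' @return An object of class `study_report`: `pcrit` (per-fish table +
#'   per-treatment paired tests + percent change), `smr` (table + tests),
#'   `p50` (per-curve fits, ANOVA table, Bohr results), `expression`
#'   (fold-change and abundance tables), `morphometry` (per-fish table +
#'   tests), and `seeds`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  s0 <- config$seed
  treatments <- c("normoxia", "hypoxia")

  masses <- with_seed(.sub_seed(s0, 1L), {
    m <- stats::rnorm(2 * config$n_per_group, config$mass_mean_g,
                      config$mass_sd_g)
    pmax(m, config$mass_mean_g / 2) / 1000  # kg
  })

  # --- respirometry: SMR + Pcrit, pre and post acclimation ---------------
  resp_rows <- list()
  for (gi in 1:2) {
    trt <- treatments[gi]
    for (fi in seq_len(config$n_per_group)) {
      mass_kg <- masses[(gi - 1) * config$n_per_group + fi]
      for (ph in c("pre", "post")) {
        key <- paste0(trt, "_", ph)
        sd_fish <- .sub_seed(s0, 2L, gi * 1000 + fi * 10 +
                               (ph == "post"))
        smr_true <- .individual(
          mo2_unit_convert(config$smr_mg_kg_h[[key]], "mg_kg_h",
                           "umol_kg_min"),
          config$individual_cv, .sub_seed(sd_fish, 1L))
        pcrit_true <- .individual(config$pcrit_mmHg[[key]],
                                  config$individual_cv,
                                  .sub_seed(sd_fish, 2L))
        res <- .fish_respirometry(smr_true, pcrit_true, mass_kg, config,
                                  .sub_seed(sd_fish, 3L))
        resp_rows[[length(resp_rows) + 1L]] <- data.frame(
          treatment = trt, fish = fi, phase = ph,
          mass_g = mass_kg * 1000,
          smr_true_mg_kg_h = mo2_unit_convert(smr_true, "umol_kg_min",
                                              "mg_kg_h"),
          pcrit_true_mmHg = pcrit_true,
          smr_mg_kg_h = res$smr_mg_kg_h, pcrit_mmHg = res$pcrit_mmHg,
          pcrit_censored = res$censored)
      }
    }
  }
  resp <- do.call(rbind, resp_rows)

  pcrit_tests <- lapply(stats::setNames(treatments, treatments),
                        function(trt) {
    pre <- resp$pcrit_mmHg[resp$treatment == trt & resp$phase == "pre"]
    post <- resp$pcrit_mmHg[resp$treatment == trt & resp$phase == "post"]
    list(test = t_test(post, pre, paired = TRUE, alternative = "less"),
         mean_pre = mean(pre), mean_post = mean(post),
         percent_change = 100 * (mean(pre) - mean(post)) / mean(pre))
  })
  smr_tests <- lapply(stats::setNames(treatments, treatments),
                      function(trt) {
    pre <- resp$smr_mg_kg_h[resp$treatment == trt & resp$phase == "pre"]
    post <- resp$smr_mg_kg_h[resp$treatment == trt & resp$phase == "post"]
    list(test = t_test(post, pre, paired = TRUE),
         mean_pre = mean(pre), sem_pre = .sem(pre),
         mean_post = mean(post), sem_post = .sem(post))
  })

  # --- hemolysate oxygen equilibria --------------------------------------
  hb_conditions <- water_conditions(22, config$salinity_psu)
  p50_rows <- list()
  bohr_rows <- list()
  for (gi in 1:2) {
    trt <- treatments[gi]
    for (fi in seq_len(config$n_per_group)) {
      sd_fish <- .sub_seed(s0, 3L, gi * 1000 + fi)
      p50_true <- .individual(config$p50_ph74[[trt]], config$individual_cv,
                              .sub_seed(sd_fish, 1L))
      plate <- simulate_oec_plate(
        p50_true, config$hill_n, config$bohr_phi,
        noise_sd = config$oec_noise_sd, conditions = hb_conditions,
        sample_id = paste0(trt, "_", fi), seed = .sub_seed(sd_fish, 2L))
      # wider saturation window: the 15-step gas series leaves few points
      # inside 0.2-0.8 at these affinities
      fits <- lapply(plate, function(cv)
        fit_hill(saturation_from_absorbance(cv), window = c(0.1, 0.9)))
      phs <- vapply(plate, function(cv) attr(cv, "ph"), numeric(1))
      for (k in seq_along(fits))
        p50_rows[[length(p50_rows) + 1L]] <- data.frame(
          treatment = trt, fish = fi, ph = phs[k],
          p50 = fits[[k]]$p50, n_h = fits[[k]]$n_h,
          r_squared = fits[[k]]$r_squared)
      bohr_rows[[length(bohr_rows) + 1L]] <- data.frame(
        treatment = trt, fish = fi,
        phi = bohr_coefficient(phs, fits = fits)$phi)
    }
  }
  p50_tab <- do.call(rbind, p50_rows)
  bohr_tab <- do.call(rbind, bohr_rows)
  p50_anova <- two_way_anova(p50_tab, "p50", "treatment", "ph")
  bohr_test <- t_test(bohr_tab$phi[bohr_tab$treatment == "hypoxia"],
                      bohr_tab$phi[bohr_tab$treatment == "normoxia"])

  # --- hemoglobin subunit expression -------------------------------------
  ct <- simulate_ct_table(config$hb_abundances, config$hb_efficiencies,
                          ref_gene = "ef1a",
                          n_samples = config$n_per_group,
                          treatment_fold_changes = config$hb_fold_changes,
                          ct_noise_sd = config$ct_noise_sd,
                          loading_sd = config$loading_sd,
                          seed = .sub_seed(s0, 4L))
  target_genes <- setdiff(names(config$hb_abundances), "ef1a")
  fold_rows <- lapply(target_genes, function(g) {
    fc <- ddct_fold_change(ct, g)
    per <- fc$per_sample
    tt <- t_test(log(per$fold[per$treatment == "hypoxia"]),
                 log(per$fold[per$treatment == "normoxia"]))
    data.frame(gene = g, mean_fold_hypoxia = fc$mean_fold[["hypoxia"]],
               sem_fold_hypoxia = fc$sem_fold[["hypoxia"]],
               p_value = tt$p_value)
  })
  fold_tab <- do.call(rbind, fold_rows)
  abund <- relative_abundance(ct, anchor_gene = "hba_3.1",
                              genes = grep("^hba", target_genes,
                                           value = TRUE))

  # --- gill morphometrics -------------------------------------------------
  morph_rows <- list()
  for (gi in 1:2) {
    trt <- treatments[gi]
    for (fi in seq_len(config$n_per_group)) {
      mass_g <- masses[(gi - 1) * config$n_per_group + fi] * 1000
      m <- simulate_morphometry(
        config$gill_area_mm2_g[[trt]], mass_g,
        spacing_cv = config$morph_cv,
        diffusion_um = config$diffusion_um[[trt]],
        diffusion_cv = config$morph_cv,
        seed = .sub_seed(s0, 5L, gi * 1000 + fi))
      res <- gill_area(m)
      morph_rows[[length(morph_rows) + 1L]] <- data.frame(
        treatment = trt, fish = fi,
        area_mm2_g = res$mass_specific_area_mm2_g,
        diffusion_um = res$diffusion$mean_um)
    }
  }
  morph_tab <- do.call(rbind, morph_rows)
  morph_tests <- list(
    area = t_test(morph_tab$area_mm2_g[morph_tab$treatment == "hypoxia"],
                  morph_tab$area_mm2_g[morph_tab$treatment == "normoxia"]),
    diffusion = t_test(
      morph_tab$diffusion_um[morph_tab$treatment == "hypoxia"],
      morph_tab$diffusion_um[morph_tab$treatment == "normoxia"]))

  structure(list(
    pcrit = list(table = resp[, c("treatment", "fish", "phase", "mass_g",
                                  "pcrit_true_mmHg", "pcrit_mmHg",
                                  "pcrit_censored")],
                 tests = pcrit_tests),
    smr = list(table = resp[, c("treatment", "fish", "phase",
                                "smr_true_mg_kg_h", "smr_mg_kg_h")],
               tests = smr_tests),
    p50 = list(table = p50_tab, anova = p50_anova,
               bohr = list(table = bohr_tab, test = bohr_test)),
    expression = list(fold_changes = fold_tab,
                      abundance = abund$group_summary),
    morphometry = list(table = morph_tab, tests = morph_tests),
    seeds = list(base = s0)),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  for (trt in names(x$pcrit$tests)) {
    tt <- x$pcrit$tests[[trt]]
    cat(sprintf("  Pcrit %s: %.1f -> %.1f mmHg (%.0f%% change), one-tailed paired p = %.3g\n",
                trt, tt$mean_pre, tt$mean_post, tt$percent_change,
                tt$test$p_value))
  }
  for (trt in names(x$smr$tests)) {
    tt <- x$smr$tests[[trt]]
    cat(sprintf("  SMR %s: %.0f +/- %.0f -> %.0f +/- %.0f mg/kg/h, paired p = %.2f\n",
                trt, tt$mean_pre, tt$sem_pre, tt$mean_post, tt$sem_post,
                tt$test$p_value))
  }
  trt_p <- x$p50$anova$p_value[x$p50$anova$effect == "treatment"]
  int_p <- x$p50$anova$p_value[grepl(":", x$p50$anova$effect)]
  cat(sprintf("  P50 ANOVA: treatment p = %.3g, interaction p = %.3g\n",
              trt_p, int_p))
  cat(sprintf("  Gill area t-test p = %.2f; diffusion p = %.2f\n",
              x$morphometry$tests$area$p_value,
              x$morphometry$tests$diffusion$p_value))
  invisible(x)
}
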