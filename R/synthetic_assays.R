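# Default tonometry O2 step set (percent O2, balanced with N2).
OEC_O2_STEPS <- c(0, 0.05, 0.1, 0.15, 0.25, 0.5, 0.75, 1, 1.5, 2,
                  5, 8, 12, 21, 100)

#' Simulate an oxygen-equilibrium plate
#'
#' Generates one absorbance-vs-PO2 curve per pH level from a Hill saturation
#' model with a pH-dependent P50 (Bohr model):
#' `log10 P50(pH) = log10 p50_at_ph74 + bohr_phi * (pH - 7.4)`,
#' `S = PO2^n / (P50^n + PO2^n)`,
#' `A = a_deoxy + (a_oxy - a_deoxy) * S + noise`.
#' The 0% and 100% O2 steps are generated as the fully deoxygenated and
#' fully oxygenated calibration plateaus (S = 0 and 1), as the saturation
#' normalization assumes.
#'
#' @param p50_at_ph74 True P50 at pH 7.4, mmHg.
#' @param hill_n True Hill coefficient (> 0).
#' @param bohr_phi True Bohr coefficient, delta log10 P50 per pH unit.
#' @param ph_levels pH levels assayed (default 7, 7.4, 7.8).
#' @param o2_steps_percent Gas steps in percent O2 (default the 15-step
#'   tonometry series from 0 to 100%).
#' @param a_deoxy,a_oxy Absorbance endpoints (must differ).
#' @param noise_sd Gaussian absorbance noise sd (default 0).
#' @param conditions A [water_conditions()] (default 22 degC, 35 psu).
#' @param humidified Humidified gas conversion (default TRUE).
#' @param sample_id Sample identifier prefix.
#' @param seed Optional integer seed.
#' @return A list of [oec_curve()] objects, one per pH, with a `truth`
#'   attribute recording the generating parameters.
#' @export
simulate_oec_plate <- function(p50_at_ph74, hill_n, bohr_phi,
                               ph_levels = c(7, 7.4, 7.8),
                               o2_steps_percent = OEC_O2_STEPS,
                               a_deoxy = 0.1, a_oxy = 0.9, noise_sd = 0,
                               conditions = water_conditions(22, 35),
                               humidified = TRUE,
                               sample_id = "sample", seed = NULL) {
  stopifnot(p50_at_ph74 > 0, hill_n > 0, a_oxy != a_deoxy, noise_sd >= 0,
            all(o2_steps_percent >= 0 & o2_steps_percent <= 100),
            0 %in% o2_steps_percent, 100 %in% o2_steps_percent)
  with_seed(seed, {
    curves <- lapply(ph_levels, function(ph) {
      p50 <- 10^(log10(p50_at_ph74) + bohr_phi * (ph - 7.4))
      po2 <- percent_o2_to_po2(o2_steps_percent, conditions, humidified)
      s <- ifelse(po2 == 0, 0, po2^hill_n / (p50^hill_n + po2^hill_n))
      # the 0% and 100% steps are the calibration plateaus the assay treats
      # as fully deoxygenated / fully oxygenated
      s[o2_steps_percent == 0] <- 0
      s[o2_steps_percent == 100] <- 1
      a <- a_deoxy + (a_oxy - a_deoxy) * s
      if (noise_sd > 0) a <- a + stats::rnorm(length(a), 0, noise_sd)
      oec_curve(o2_steps_percent, po2, a, ph = ph,
                temperature_C = conditions$temperature_C,
                sample_id = paste0(sample_id, "_pH", ph))
    })
    names(curves) <- paste0("pH", ph_levels)
    attr(curves, "truth") <- list(p50_at_ph74 = p50_at_ph74, hill_n = hill_n,
                                  bohr_phi = bohr_phi)
    curves
  })
}

#' Simulate a qPCR Ct table
#'
#' Ct values are generated from true transcript amounts under per-primer
#' amplification efficiencies: a transcript present at amount `X` with
#' efficiency `E` crosses the common fluorescence threshold at
#' `ct = (ln N_threshold - ln X) / ln E`, so `E^ct = N_threshold / X` and the
#' anchored ratio `E_a^ct_a / E_n^ct_n` recovers `X_n / X_a` exactly at zero
#' noise. Treatment fold changes multiply the treated group's amounts; a
#' per-sample loading factor (lognormal, sd `loading_sd` on the log scale)
#' multiplies every gene of a sample and is absorbed by the reference gene.
#'
#' @param abundances Named vector of true relative transcript amounts
#'   (> 0); must include `ref_gene`.
#' @param efficiencies Named vector of per-primer efficiencies in (1, 2\],
#'   same names as `abundances`.
#' @param ref_gene Reference (internal control) gene name, default `"ef1a"`.
#' @param n_samples Samples per treatment group (default 7).
#' @param treatment_fold_changes Named vector of fold changes applied to the
#'   treated (hypoxia) group; genes not named get fold 1. The reference gene
#'   is always fold 1.
#' @param ct_noise_sd Gaussian Ct noise sd in cycles (default 0).
#' @param loading_sd sd of the per-sample log-normal loading offset
#'   (default 0).
#' @param threshold_log2 log2 of the threshold amount relative to unit
#'   abundance (default 28, i.e. Ct 28 for abundance 1 at E = 2).
#' @param seed Optional integer seed.
#' @return A `data.frame` of class `ct_table` with columns `sample_id`,
#'   `treatment` (`"normoxia"`/`"hypoxia"`), `gene`, `ct`, `efficiency`, the
#'   reference gene recorded in attribute `ref_gene` and the generating
#'   parameters in attribute `truth`.
#' @export
simulate_ct_table <- function(abundances, efficiencies, ref_gene = "ef1a",
                              n_samples = 7,
                              treatment_fold_changes = NULL,
                              ct_noise_sd = 0, loading_sd = 0,
                              threshold_log2 = 28, seed = NULL) {
  stopifnot(!is.null(names(abundances)), all(abundances > 0),
            !is.null(names(efficiencies)),
            setequal(names(abundances), names(efficiencies)),
            ref_gene %in% names(abundances), n_samples >= 1,
            ct_noise_sd >= 0, loading_sd >= 0)
  if (any(efficiencies <= 1 | efficiencies > 2))
    stop("efficiencies must lie in (1, 2]", call. = FALSE)
  genes <- names(abundances)
  fold <- stats::setNames(rep(1, length(genes)), genes)
  if (!is.null(treatment_fold_changes)) {
    stopifnot(all(names(treatment_fold_changes) %in% genes),
              all(treatment_fold_changes > 0))
    fold[names(treatment_fold_changes)] <- treatment_fold_changes
  }
  fold[ref_gene] <- 1
  ln_thr <- threshold_log2 * log(2)
  with_seed(seed, {
    rows <- list()
    for (trt in c("normoxia", "hypoxia")) {
      for (s in seq_len(n_samples)) {
        loading <- if (loading_sd > 0) exp(stats::rnorm(1, 0, loading_sd))
        else 1
        x <- abundances * loading *
          (if (trt == "hypoxia") fold else rep(1, length(genes)))
        ct <- (ln_thr - log(x)) / log(efficiencies[genes])
        if (ct_noise_sd > 0)
          ct <- ct + stats::rnorm(length(ct), 0, ct_noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_%d", trt, s), treatment = trt,
          gene = genes, ct = unname(ct),
          efficiency = unname(efficiencies[genes]))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "ref_gene") <- ref_gene
    attr(out, "truth") <- list(abundances = abundances, fold = fold,
                               threshold_log2 = threshold_log2)
    class(out) <- c("ct_table", "data.frame")
    out
  })
}

#' Simulate a gill morphometry measurement set
#'
#' Builds filament lengths (every-10th sampling), interlamellar spacing and
#' bilateral lamellar areas whose Hughes product `L * f * B` equals
#' `true_area_per_mass * mass_g` exactly at zero variance and in expectation
#' otherwise (spacing noise enters only through `2/mean(spacing)`, whose
#' bias is O(cv^2/n) and negligible at the default measurement counts).
#'
#' @param true_area_per_mass True mass-specific gill area, mm^2 g^-1.
#' @param mass_g Body mass, g.
#' @param n_filaments Filament count on the first arch (default 120).
#' @param spacing_cv Coefficient of variation of the spacing measurements
#'   (default 0).
#' @param mean_filament_mm Mean filament length (default 9 mm).
#' @param mean_spacing_mm Mean one-side interlamellar spacing (default
#'   0.05 mm, i.e. 40 lamellae per mm counting both sides).
#' @param n_spacing Number of spacing measurements (default 24).
#' @param n_lamellae Number of lamellar area measurements (default 20).
#' @param n_images,n_per_image Diffusion-distance sampling design (default
#'   15 images x 10 measurements).
#' @param diffusion_um True diffusion distance (default 1.22 um).
#' @param diffusion_cv CV of the diffusion measurements (default 0).
#' @param seed Optional integer seed.
#' @return An object of class `gill_morphometry` with a `truth` attribute.
#' @export
simulate_morphometry <- function(true_area_per_mass, mass_g,
                                 n_filaments = 120, spacing_cv = 0,
                                 mean_filament_mm = 9,
                                 mean_spacing_mm = 0.05,
                                 n_spacing = 24, n_lamellae = 20,
                                 n_images = 15, n_per_image = 10,
                                 diffusion_um = 1.22, diffusion_cv = 0,
                                 seed = NULL) {
  stopifnot(true_area_per_mass > 0, mass_g > 0, n_filaments >= 10,
            spacing_cv >= 0, mean_filament_mm > 0, mean_spacing_mm > 0)
  with_seed(seed, {
    positions <- seq(10L, n_filaments, by = 10L)
    lengths <- rep(mean_filament_mm, length(positions))
    total_l <- n_filaments * mean_filament_mm
    f_true <- 2 / mean_spacing_mm
    area_total <- true_area_per_mass * mass_g
    b_true <- area_total / (total_l * f_true)
    spacing <- if (spacing_cv > 0)
      abs(stats::rnorm(n_spacing, mean_spacing_mm,
                       spacing_cv * mean_spacing_mm))
    else rep(mean_spacing_mm, n_spacing)
    areas <- rep(b_true, n_lamellae)
    diff_vals <- if (diffusion_cv > 0)
      abs(stats::rnorm(n_images * n_per_image, diffusion_um,
                       diffusion_cv * diffusion_um))
    else rep(diffusion_um, n_images * n_per_image)
    morph <- gill_morphometry(
      n_filaments = n_filaments,
      filament_positions = positions,
      filament_lengths_mm = lengths,
      spacing_mm = spacing,
      lamellar_areas_mm2 = areas,
      diffusion_um = data.frame(image = rep(seq_len(n_images),
                                            each = n_per_image),
                                value_um = diff_vals),
      body_mass_g = mass_g)
    attr(morph, "truth") <- list(area_per_mass = true_area_per_mass,
                                 diffusion_um = diffusion_um)
    morph
  })
}
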