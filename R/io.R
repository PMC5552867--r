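#' Read / write an oxygen trace CSV
#'
#' Trace CSV dialect: header `time_min, po2_mmHg, phase, cycle`, decimal
#' point, comma separator.
#'
#' @param path File path.
#' @return [read_o2_trace()] returns an [o2_trace()].
#' @export
read_o2_trace <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "po2_mmHg", "phase", "cycle")
  if (!all(need %in% names(df)))
    stop("trace CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  o2_trace(df$time_min, df$po2_mmHg, df$phase, df$cycle)
}

#' @rdname read_o2_trace
#' @param trace An [o2_trace()].
#' @export
write_o2_trace <- function(trace, path) {
  stopifnot(inherits(trace, "o2_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Read an oxygen-equilibrium plate CSV
#'
#' Plate CSV dialect: one row per equilibration step, columns `sample_id,
#' ph, gas_percent_o2, absorbance`; PO2 is derived from the gas step via
#' [percent_o2_to_po2()].
#'
#' @param path File path.
#' @param conditions A [water_conditions()] for the gas conversion.
#' @param humidified Humidified gas conversion (default TRUE).
#' @return A list of [oec_curve()] objects, one per (sample_id, ph).
#' @export
read_oec_plate <- function(path, conditions, humidified = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "ph", "gas_percent_o2", "absorbance")
  if (!all(need %in% names(df)))
    stop("plate CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  keys <- unique(df[, c("sample_id", "ph")])
  curves <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$sample_id == keys$sample_id[i] & df$ph == keys$ph[i], ]
    oec_curve(sub$gas_percent_o2,
              percent_o2_to_po2(sub$gas_percent_o2, conditions, humidified),
              sub$absorbance, ph = keys$ph[i],
              temperature_C = conditions$temperature_C,
              sample_id = keys$sample_id[i])
  })
  names(curves) <- paste0(keys$sample_id, "_pH", keys$ph)
  curves
}

#' Read a Ct table CSV
#'
#' Ct CSV dialect: columns `sample_id, treatment, gene, ct, efficiency`;
#' empty/NA ct marks an undetectable (censored) transcript.
#'
#' @param path File path.
#' @param ref_gene Reference gene name.
#' @return A [ct_table()].
#' @export
read_ct_table <- function(path, ref_gene) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ct_table(df, ref_gene)
}

#' Read / write a gill morphometry CSV
#'
#' Morphometry CSV dialect: one row per measurement, columns
#' `measurement_type` (`filament_length`, `spacing`, `lamellar_area`,
#' `diffusion`), `value` (mm, mm, mm^2, um respectively) and `index`
#' (filament position for lengths, image index for diffusion).
#'
#' @param path File path.
#' @param n_filaments Total filament count on the first arch.
#' @param body_mass_g Body mass in g.
#' @return A [gill_morphometry()].
#' @export
read_gill_morphometry <- function(path, n_filaments, body_mass_g) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("measurement_type", "value", "index")
  if (!all(need %in% names(df)))
    stop("morphometry CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  fl <- df[df$measurement_type == "filament_length", ]
  dif <- df[df$measurement_type == "diffusion", ]
  gill_morphometry(
    n_filaments = n_filaments,
    filament_positions = fl$index,
    filament_lengths_mm = fl$value,
    spacing_mm = df$value[df$measurement_type == "spacing"],
    lamellar_areas_mm2 = df$value[df$measurement_type == "lamellar_area"],
    diffusion_um = data.frame(image = dif$index, value_um = dif$value),
    body_mass_g = body_mass_g)
}

#' @rdname read_gill_morphometry
#' @param morph A [gill_morphometry()].
#' @export
write_gill_morphometry <- function(morph, path) {
  stopifnot(inherits(morph, "gill_morphometry"))
  df <- rbind(
    data.frame(measurement_type = "filament_length",
               value = morph$filament_lengths_mm,
               index = morph$filament_positions),
    data.frame(measurement_type = "spacing", value = morph$spacing_mm,
               index = seq_along(morph$spacing_mm)),
    data.frame(measurement_type = "lamellar_area",
               value = morph$lamellar_areas_mm2,
               index = seq_along(morph$lamellar_areas_mm2)),
    data.frame(measurement_type = "diffusion",
               value = morph$diffusion_um$value_um,
               index = morph$diffusion_um$image))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a study configuration from YAML
#'
#' Reads a YAML file whose top-level keys are [study_config()] arguments
#' and builds the configuration, so pipeline runs are reproducible from a
#' plain-text file.
#'
#' @param path YAML file path.
#' @return A `study_config` object.
#' @export
read_study_config <- function(path) {
  args <- yaml::read_yaml(path)
  for (nm in c("hb_abundances", "hb_efficiencies", "hb_fold_changes"))
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  do.call(study_config, args)
}
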