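#' Convert a gas-phase percent O2 to partial pressure
#'
#' For tonometry gas steps: `gas_percent/100 * P`, where `P` is barometric
#' pressure minus the saturated water vapor pressure when `humidified = TRUE`
#' (the default for gas equilibrated with an aqueous sample), or barometric
#' pressure unchanged when dry.
#'
#' @param gas_percent Percent O2 of the gas mixture, in \[0, 100\]. Vectorized.
#' @param conditions A [water_conditions()] object.
#' @param humidified Is the gas water-saturated? Default TRUE.
#' @return PO2 in mmHg.
#' @examples
#' percent_o2_to_po2(21, water_conditions(22, 0), humidified = FALSE) # 159.6
#' @export
percent_o2_to_po2 <- function(gas_percent, conditions, humidified = TRUE) {
  stopifnot(inherits(conditions, "water_conditions"),
            is.numeric(gas_percent))
  if (any(gas_percent < 0 | gas_percent > 100))
    stop("gas_percent must lie in [0, 100]", call. = FALSE)
  p <- conditions$barometric_mmHg
  if (humidified) p <- p - water_vapor_pressure(conditions)
  gas_percent / 100 * p
}

#' Construct / validate an oxygen equilibrium curve
#'
#' One hemolysate's absorbance-vs-oxygen-tension table at a known pH and
#' temperature. Must include a 0% (fully deoxygenated) and a 100% (fully
#' oxygenated) endpoint, which anchor the saturation normalization.
#'
#' @param gas_percent_o2 Percent O2 of each equilibration step.
#' @param po2_mmHg Oxygen partial pressure of each step (strictly increasing
#'   with `gas_percent_o2`).
#' @param absorbance Absorbance plateau at each step.
#' @param ph Hemolysate pH.
#' @param temperature_C Assay temperature.
#' @param sample_id Sample identifier.
#' @return A `data.frame` of class `oec_curve` with the per-step columns and
#'   `ph`, `temperature_C`, `sample_id` attributes.
#' @export
oec_curve <- function(gas_percent_o2, po2_mmHg, absorbance, ph,
                      temperature_C = 22, sample_id = "sample") {
  stopifnot(is.numeric(gas_percent_o2), is.numeric(po2_mmHg),
            is.numeric(absorbance),
            length(gas_percent_o2) == length(po2_mmHg),
            length(absorbance) == length(po2_mmHg))
  ord <- order(gas_percent_o2)
  gas_percent_o2 <- gas_percent_o2[ord]
  po2_mmHg <- po2_mmHg[ord]
  absorbance <- absorbance[ord]
  if (gas_percent_o2[1L] != 0 || gas_percent_o2[length(gas_percent_o2)] != 100)
    stop("oec_curve needs 0% and 100% O2 endpoints", call. = FALSE)
  if (any(diff(po2_mmHg) <= 0))
    stop("po2 must increase strictly with gas_percent_o2", call. = FALSE)
  out <- data.frame(gas_percent_o2 = gas_percent_o2, po2_mmHg = po2_mmHg,
                    absorbance = absorbance)
  attr(out, "ph") <- ph
  attr(out, "temperature_C") <- temperature_C
  attr(out, "sample_id") <- sample_id
  class(out) <- c("oec_curve", "data.frame")
  out
}

#' Fractional saturation from absorbance plateaus
#'
#' Normalizes each step's absorbance between the deoxygenated (0% O2) and
#' oxygenated (100% O2) endpoints: `S = (A - A0) / (A100 - A0)`. Values
#' outside \[0, 1\] (possible under noise) are reported as-is and flagged,
#' never clipped silently.
#'
#' @param curve An [oec_curve()].
#' @return A `data.frame` with `po2_mmHg`, `saturation` and `out_of_range`
#'   for the non-endpoint steps.
#' @export
saturation_from_absorbance <- function(curve) {
  stopifnot(inherits(curve, "oec_curve"))
  a0 <- curve$absorbance[curve$gas_percent_o2 == 0][1L]
  a100 <- curve$absorbance[curve$gas_percent_o2 == 100][1L]
  if (a100 == a0)
    stop("coincident endpoints: no absorbance dynamic range", call. = FALSE)
  mid <- curve$gas_percent_o2 > 0 & curve$gas_percent_o2 < 100
  s <- (curve$absorbance[mid] - a0) / (a100 - a0)
  data.frame(po2_mmHg = curve$po2_mmHg[mid], saturation = s,
             out_of_range = s < 0 | s > 1)
}

#' Hill fit of an oxygen equilibrium curve
#'
#' Ordinary least squares on the Hill transform `log10(S/(1-S))` versus
#' `log10(PO2)` over the points whose saturation lies inside `window`
#' (default 0.2-0.8, the quasi-linear central region of the Hill plot).
#' P50 = 10^(-intercept/slope); the slope is the Hill coefficient n_H.
#'
#' @param sat A `data.frame` with columns `po2_mmHg` and `saturation`
#'   (output of [saturation_from_absorbance()]).
#' @param window Saturation window (exclusive bounds), default `c(0.2, 0.8)`.
#' @return An object of class `hill_fit`: `n_h` (slope), `intercept`, `p50`,
#'   `r_squared`, `n_points`, `window`, and `p50_interpolated` (a direct
#'   monotone interpolation of S = 0.5, emitted as a diagnostic).
#' @export
fit_hill <- function(sat, window = c(0.2, 0.8)) {
  stopifnot(is.data.frame(sat), all(c("po2_mmHg", "saturation") %in%
                                      names(sat)),
            length(window) == 2L, window[1] < window[2])
  ok <- sat$saturation > window[1] & sat$saturation < window[2] &
    sat$saturation > 0 & sat$saturation < 1 & sat$po2_mmHg > 0
  pts <- sat[ok, , drop = FALSE]
  if (nrow(pts) < 3L)
    stop(sprintf("fit_hill needs >= 3 points inside the (%.2f, %.2f) window, got %d",
                 window[1], window[2], nrow(pts)), call. = FALSE)
  x <- log10(pts$po2_mmHg)
  y <- log10(pts$saturation / (1 - pts$saturation))
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  # monotone-interpolation cross-check of the half-saturation point
  p50_int <- NA_real_
  s_all <- sat[order(sat$po2_mmHg), ]
  cross <- which(diff(s_all$saturation >= 0.5) == 1)
  if (length(cross) >= 1L) {
    i <- cross[1L]
    p50_int <- stats::approx(s_all$saturation[c(i, i + 1L)],
                             s_all$po2_mmHg[c(i, i + 1L)], xout = 0.5)$y
  }
  structure(list(n_h = unname(co[2L]), intercept = unname(co[1L]),
                 p50 = 10^(-co[[1L]] / co[[2L]]),
                 r_squared = r2,
                 n_points = nrow(pts), window = window,
                 p50_interpolated = p50_int),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> P50 = %.2f mmHg, n_H = %.2f (R2 = %.4f, %d points in S window %.2f-%.2f)\n",
              x$p50, x$n_h, x$r_squared, x$n_points,
              x$window[1], x$window[2]))
  invisible(x)
}

#' Bohr coefficient from P50 values across pH
#'
#' phi = d log10(P50) / d pH, fitted by OLS across all available (pH, P50)
#' pairs; with exactly two pH values this equals the pairwise
#' `delta log10 P50 / delta pH` exactly. Pairwise coefficients for every pH
#' pair are also reported.
#'
#' @param ph Numeric vector of hemolysate pH values (>= 2 distinct).
#' @param p50 Matching P50 values in mmHg (or a list of `hill_fit` objects
#'   passed via `fits` instead).
#' @param fits Optional list of `hill_fit` objects, used with `ph` in place
#'   of `p50`.
#' @return An object of class `bohr_result`: `phi`, `ph`, `p50`,
#'   `pairwise` (data.frame of all pH pairs) and `method`.
#' @export
bohr_coefficient <- function(ph, p50 = NULL, fits = NULL) {
  if (is.null(p50)) {
    stopifnot(is.list(fits), all(vapply(fits, inherits, TRUE, "hill_fit")))
    p50 <- vapply(fits, function(f) f$p50, numeric(1))
  }
  stopifnot(is.numeric(ph), is.numeric(p50), length(ph) == length(p50),
            all(p50 > 0))
  if (length(unique(ph)) < 2L)
    stop("bohr_coefficient needs >= 2 distinct pH values", call. = FALSE)
  fit <- stats::lm(log10(p50) ~ ph)
  pairs <- utils::combn(seq_along(ph), 2L)
  keep <- ph[pairs[1L, ]] != ph[pairs[2L, ]]
  pairs <- pairs[, keep, drop = FALSE]
  pw <- data.frame(
    ph_low = pmin(ph[pairs[1L, ]], ph[pairs[2L, ]]),
    ph_high = pmax(ph[pairs[1L, ]], ph[pairs[2L, ]]),
    phi = (log10(p50[pairs[2L, ]]) - log10(p50[pairs[1L, ]])) /
      (ph[pairs[2L, ]] - ph[pairs[1L, ]]))
  structure(list(phi = unname(stats::coef(fit)[2L]), ph = ph, p50 = p50,
                 pairwise = pw, method = "ols"),
            class = "bohr_result")
}

#' @export
print.bohr_result <- function(x, ...) {
  cat(sprintf("<bohr_result> phi = %.4f (OLS over %d pH values)\n",
              x$phi, length(x$ph)))
  invisible(x)
}
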