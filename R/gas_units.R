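#' Water conditions for gas calculations
#'
#' Bundles the physical water conditions every gas conversion in the package
#' depends on: temperature, salinity and barometric pressure.
#'
#' @param temperature_C Water temperature in degrees Celsius, in \[0, 40\].
#' @param salinity_psu Salinity in practical salinity units, in \[0, 40\].
#' @param barometric_mmHg Barometric pressure in mmHg (default 760).
#'
#' @return An object of class `water_conditions`.
#' @examples
#' water_conditions(24, 35)
#' @export
water_conditions <- function(temperature_C, salinity_psu = 0,
                             barometric_mmHg = 760) {
  stopifnot(is.numeric(temperature_C), length(temperature_C) == 1L,
            is.numeric(salinity_psu), length(salinity_psu) == 1L,
            is.numeric(barometric_mmHg), length(barometric_mmHg) == 1L)
  if (temperature_C < 0 || temperature_C > 40)
    stop("temperature_C must lie in [0, 40] degC", call. = FALSE)
  if (salinity_psu < 0 || salinity_psu > 40)
    stop("salinity_psu must lie in [0, 40] psu", call. = FALSE)
  if (barometric_mmHg <= 0)
    stop("barometric_mmHg must be positive", call. = FALSE)
  structure(list(temperature_C = temperature_C,
                 salinity_psu = salinity_psu,
                 barometric_mmHg = barometric_mmHg),
            class = "water_conditions")
}

#' @export
print.water_conditions <- function(x, ...) {
  cat(sprintf("<water_conditions> %.1f degC, %.1f psu, %.0f mmHg\n",
              x$temperature_C, x$salinity_psu, x$barometric_mmHg))
  invisible(x)
}

# Mole fraction of O2 in dry air.
O2_AIR_FRACTION <- 0.2095

# Molar volume of O2 at STP used by the solubility correlation (L/mol).
O2_MOLAR_VOLUME_STP <- 22.3916

#' Saturated water vapor pressure
#'
#' Weiss & Price (1980, Mar. Chem. 8:347) formulation of the vapor pressure
#' of water over seawater, the one bundled with the oxygen solubility
#' correlation used by [o2_solubility()].
#'
#' @param conditions A [water_conditions()] object.
#' @return Vapor pressure in mmHg.
#' @examples
#' water_vapor_pressure(water_conditions(22, 0)) # ~19.8 mmHg
#' @export
water_vapor_pressure <- function(conditions) {
  stopifnot(inherits(conditions, "water_conditions"))
  tk <- conditions$temperature_C + 273.15
  p_atm <- exp(24.4543 - 67.4509 * (100 / tk) - 4.8489 * log(tk / 100) -
                 0.000544 * conditions$salinity_psu)
  p_atm * 760
}

#' Oxygen solubility coefficient in water
#'
#' Returns the solubility of oxygen, alpha, in umol L^-1 mmHg^-1 at the given
#' temperature and salinity, from the Garcia & Gordon (1992, Limnol.
#' Oceanogr. 37:1307) re-fit of the Benson & Krause data (volumetric
#' coefficients, converted from mL/L via the 22.3916 L/mol molar volume).
#' The saturation concentration is referenced to water-saturated air at the
#' stated barometric pressure, so alpha = C_sat / (0.2095 * (P - pH2O)).
#'
#' @param conditions A [water_conditions()] object.
#' @return Solubility in umol L^-1 mmHg^-1 (scalar, positive).
#' @examples
#' o2_solubility(water_conditions(24, 35)) # ~1.39 umol/L/mmHg
#' @export
o2_solubility <- function(conditions) {
  stopifnot(inherits(conditions, "water_conditions"))
  tt <- conditions$temperature_C
  s <- conditions$salinity_psu
  ts <- log((298.15 - tt) / (273.15 + tt))
  A <- c(2.00907, 3.22014, 4.05010, 4.94457, -2.56847e-1, 3.88767)
  B <- c(-6.24523e-3, -7.37614e-3, -1.03410e-2, -8.17083e-3)
  C0 <- -4.88682e-7
  ln_c <- sum(A * ts^(0:5)) + s * sum(B * ts^(0:3)) + C0 * s^2
  c_sat_umol_l <- exp(ln_c) * 1000 / O2_MOLAR_VOLUME_STP
  po2_sat <- O2_AIR_FRACTION *
    (conditions$barometric_mmHg - water_vapor_pressure(conditions))
  c_sat_umol_l / po2_sat
}

#' Convert percent air saturation to oxygen partial pressure
#'
#' The dry-gas conversion (the default) is percent/100 * 0.2095 * barometric
#' pressure; with `vapor_corrected = TRUE` the saturated water vapor pressure
#' at the given temperature is subtracted from barometric pressure first.
#'
#' @param percent_airsat Percent air saturation, in \[0, 100\]. Vectorized.
#' @param conditions A [water_conditions()] object.
#' @param vapor_corrected Subtract water vapor pressure first? Default FALSE.
#' @return PO2 in mmHg.
#' @examples
#' airsat_to_po2(8, water_conditions(24, 35))   # 12.7 mmHg
#' airsat_to_po2(30, water_conditions(22, 35))  # ~48 mmHg
#' @export
airsat_to_po2 <- function(percent_airsat, conditions,
                          vapor_corrected = FALSE) {
  stopifnot(inherits(conditions, "water_conditions"),
            is.numeric(percent_airsat))
  if (any(percent_airsat < 0 | percent_airsat > 100))
    stop("percent_airsat must lie in [0, 100]", call. = FALSE)
  p <- conditions$barometric_mmHg
  if (vapor_corrected) p <- p - water_vapor_pressure(conditions)
  percent_airsat / 100 * O2_AIR_FRACTION * p
}

# Conversion factor between umol O2 kg-1 min-1 and mgO2 kg-1 h-1:
# 32 g/mol molar mass, 60 min/h -> 1 umol/kg/min = 1.92 mg/kg/h.
MO2_UMOL_MIN_TO_MG_H <- 60 * 32 / 1000

#' Convert oxygen uptake rate between unit systems
#'
#' Converts mass-specific MO2 between the chamber-equation units
#' (umol kg^-1 min^-1) and the reporting units (mgO2 kg^-1 h^-1), using
#' the 32 g/mol molar mass of O2 and 60 min/h. The round trip is exact.
#'
#' @param value MO2 value(s).
#' @param from,to Unit labels, one of `"umol_kg_min"` or `"mg_kg_h"`.
#' @return Converted value(s).
#' @examples
#' mo2_unit_convert(1, "umol_kg_min", "mg_kg_h") # 1.92
#' @export
mo2_unit_convert <- function(value, from, to) {
  units <- c("umol_kg_min", "mg_kg_h")
  from <- match.arg(from, units)
  to <- match.arg(to, units)
  stopifnot(is.numeric(value))
  if (from == to) return(value)
  if (from == "umol_kg_min") value * MO2_UMOL_MIN_TO_MG_H
  else value / MO2_UMOL_MIN_TO_MG_H
}
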