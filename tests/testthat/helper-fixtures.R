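# Shared fixtures: standard study water conditions and a default chamber.
std_conditions <- function() water_conditions(24, 35)

std_setup <- function(mass_kg = 0.091, v = 2.5)
  chamber_setup(v, mass_kg, std_conditions())

# SMR of the normoxia pre-acclimation group, in chamber-equation units.
std_smr_umol <- function() mo2_unit_convert(151, "mg_kg_h", "umol_kg_min")

# Saturation table on a dense PO2 grid from an exact Hill model.
hill_sat <- function(p50, n, po2 = exp(seq(log(1), log(150), length.out = 40)))
  data.frame(po2_mmHg = po2, saturation = po2^n / (p50^n + po2^n))
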