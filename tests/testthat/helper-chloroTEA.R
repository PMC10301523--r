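# Shared fixtures: default coefficient set and a small deterministic
# culture stream builder used across flowsheet tests.

default_cc <- calibration_coefficients()

make_culture_stream <- function(vol_l_h = 8160, biomass_g_l = 1.57,
                                chl_ug_l = 12970, glucose_g_l = 0.5) {
  bio <- biomass_g_l * vol_l_h / 1000
  chl <- chl_ug_l * vol_l_h / 1e9
  glu <- glucose_g_l * vol_l_h / 1000
  stream(vol_l_h, dry_biomass = bio, chlorophyll = chl, glucose = glu,
         water = vol_l_h - bio - chl - glu)
}

stream_total_mass <- function(s) sum(s$mass)
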