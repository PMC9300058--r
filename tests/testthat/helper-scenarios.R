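# Shared fixtures: scenario presets and deterministic modifications.

preset <- function(name, ...) {
  cfg <- scenario_preset(name)
  mods <- list(...)
  for (nm in names(mods)) cfg[[nm]] <- mods[[nm]]
  cfg
}

zero_by_trait <- list(mass_g = 0, head_mm = 0, tarsus_mm = 0)

# a noiseless variant: every record sits exactly on its growth curve
noise_free <- function(name = "barents", ...) {
  preset(name,
         sd_cohort = zero_by_trait, sd_nest = zero_by_trait,
         sd_residual = zero_by_trait, hatchdate_slope = zero_by_trait,
         apply_rounding = FALSE, ...)
}

# small instance for slow model-fitting tests
desk <- function(name = "barents", n = 120, ...) {
  preset(name, n_goslings_target = n, ...)
}

barents_coords <- data.frame(population = "barents",
                             latitude_deg = 68.583,
                             longitude_deg = 52.333)
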