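# Shared tiny fixtures, all generated in code.

tiny_atlas <- function(n_regions = 1, radius = 2) {
  specs <- list(list(name = "R1", center = c(4, 4, 4), radius = radius),
                list(name = "R2", center = c(9, 4, 4), radius = radius))
  make_atlas(c(12, 8, 8), region_specs = specs[seq_len(n_regions)])
}

# one-region effect spec with explicit NA/NV/NR amplitudes
tiny_spec <- function(amp = c(1, 0.5, 0.2), pattern_sd = 0, region = "R1",
                      seed_base = 101L) {
  effect_spec(region,
              amplitude = matrix(amp, 1, 3,
                                 dimnames = list(region, c("NA", "NV", "NR"))),
              pattern_sd = pattern_sd, pattern_seed_base = seed_base)
}

quiet_noise <- function() {
  noise_spec(white_sd = 0, ar1_rho = 0, drift_amplitude = 0,
             motion_coupling = 0)
}

# small in-memory null cohort on a one-region grid
tiny_null_cohort <- function(n_subjects = 4, seed = 7,
                             noise = noise_spec(), atlas = tiny_atlas()) {
  b <- build_design()
  simulate_cohort(n_subjects, b$design, atlas,
                  tiny_spec(amp = c(0.9, 0.9, 0.2)), noise,
                  events = b$events, between_subject_sd = 0.2, seed = seed)
}
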