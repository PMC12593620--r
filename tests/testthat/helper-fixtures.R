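# Shared fixtures: the reference calibration triple and small, fast scenarios.

ref_calib <- function() calibration_params(0.916, 0.408, 0.497)

ref_model <- function() make_fluorophore_model(ref_calib())

# Small field for unit tests: 128 px, 6 cells, defaults otherwise.
small_scenario <- function(seed = 1L, ...) {
  sim_scenario(cells_per_field = 6, image_size = 128, seed = seed, ...)
}

# Noise-free, background-free scenario: rendered intensities are exact.
exact_scenario <- function(seed = 1L, ...) {
  sim_scenario(cells_per_field = 6, image_size = 128, noise = FALSE,
               background = 0, seed = seed, ...)
}

random_fluorophore_model <- function() {
  b_red <- runif(1, 0.5, 2)
  b_ox <- runif(1, 0.2, 2)
  r_red <- runif(1, 0.2, 1)
  r_ox <- r_red + runif(1, 0.2, 2)
  fluorophore_model(a_ox = r_ox * b_ox, a_red = r_red * b_red,
                    b_ox = b_ox, b_red = b_red)
}
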