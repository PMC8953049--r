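# Small, fast phantom configurations shared across the suite.

clean_spec <- function(...) {
  # noise-free, blur-free: the exactly piecewise-constant construction
  phantom_spec(grid_shape = c(32, 32, 32), blood_activity = 10000,
               vascular_fraction = 0.1, psf_sigma_mm = 0, noise = "none", ...)
}

noisy_spec <- function(..., dwell_scale = 1) {
  phantom_spec(grid_shape = c(32, 32, 32), blood_activity = 20000,
               vascular_fraction = 0.1, psf_sigma_mm = 0, noise = "poisson",
               dwell_scale = dwell_scale, ...)
}

diastole <- function(ph) ph$gates[[ph$diastolic_gate_index]]

# uniform random volume on a fixed seed, for round-trip checks
seeded_volume <- function(seed, shape = c(8, 9, 10), unit = "Bq_per_mL") {
  withr::with_seed(seed,
    volume_grid(array(runif(prod(shape), 0, 100), dim = shape),
                voxel_size_mm = 1.4, unit = unit))
}
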