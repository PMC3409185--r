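# Shared small fixtures, built lazily and cached for the whole test run.
.fixtures <- new.env(parent = emptyenv())

fix_head <- function() head_model()

fix_sensors <- function(n = 32) {
  key <- paste0("sens", n)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- build_sensor_array(n, head = fix_head())
  .fixtures[[key]]
}

# occipital ROI grid at the given spacing, with its lead fields
fix_roi <- function(spacing = 5, n_sensors = 32) {
  key <- sprintf("roi_%g_%d", spacing, n_sensors)
  if (is.null(.fixtures[[key]])) {
    g <- crop_grid(build_source_grid(spacing, fix_head(), 5, 20),
                   c(15, -105, -20), c(55, -65, 20))
    .fixtures[[key]] <- list(
      grid = g, lf = lead_field_matrix(g, fix_sensors(n_sensors), fix_head()))
  }
  .fixtures[[key]]
}

# one induced gamma source; baseline > 0 makes gain a power modulator
gamma_source <- function(loc = c(35, -85, 0), amplitude = 20, baseline = 0,
                         carrier = "noise", phase_jitter = 1) {
  source_spec(loc, orientation = 0.4, components = list(
    source_component("induced", freq = 60, bandwidth = 20, onset = 150,
                     offset = 650, amplitude = amplitude,
                     baseline_amplitude = baseline, carrier = carrier,
                     phase_jitter = phase_jitter)))
}

# small epoch set of pure white sensor noise
noise_epochs <- function(n_epochs = 10, n_ch = 4, n_t = 400, sfreq = 678.17,
                         sd = 1, seed = 1) {
  withr::with_seed(seed, {
    dat <- array(stats::rnorm(n_epochs * n_ch * n_t, sd = sd),
                 c(n_epochs, n_ch, n_t))
  })
  epoch_set(dat, sfreq, seq(-1000, by = 1000 / sfreq, length.out = n_t))
}
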