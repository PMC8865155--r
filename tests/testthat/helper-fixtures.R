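# Shared fixtures: small configurations and noise-free ground truths built
# in code at test time.

small_config <- function(...) {
  design_config(n_participants = 2L, rng_seed = 7L, ...)
}

# Noise-free truth with a single oxygenation response injected in one
# (condition, hemisphere) cell.
truth_single_cell <- function(condition = "AO+MI", hemisphere = "left",
                              amplitude = 1.0, ...) {
  amp <- matrix(0, 2, 4,
                dimnames = list(c("left", "right"),
                                c("AO", "MI", "AO+MI", "IMIT")))
  amp[hemisphere, condition] <- amplitude
  ground_truth(
    oxy_amplitude = amp,
    fnirs_noise = noise_off(),
    tempo_sd_log = 0, jitter_sd = 0, p_invalid = 0,
    ...
  )
}

noise_off <- function() {
  list(cardiac = 0, respiratory = 0, mayer = 0, white = 0,
       cardiac_hz = 1.1, respiratory_hz = 0.3, mayer_hz = 0.1)
}

truth_noise_free <- function(...) {
  ground_truth(fnirs_noise = noise_off(), tempo_sd_log = 0, jitter_sd = 0,
               p_invalid = 0, ...)
}

# Amplitude of a sinusoidal steady-state response, read off away from the
# filter edges.
steady_amplitude <- function(x, trim = 0.2) {
  n <- length(x)
  core <- x[ceiling(n * trim):floor(n * (1 - trim))]
  (max(core) - min(core)) / 2
}
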