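# Forward fNIRS model: known per-(condition, hemisphere) oxygenation
# responses are shaped by a canonical HRF, converted to optical density via
# the same Beer-Lambert convention the inverse uses, and embedded in raw
# two-wavelength intensities with physiological and instrumental noise.

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities in the standard convention: response
#' delay and undershoot delay are the gamma shape parameters (unit rate),
#' with the undershoot scaled down by `ratio`. The kernel is normalized to
#' unit peak; absolute scale is irrelevant here because injected responses
#' are calibrated on the capture-window mean.
#'
#' @param t time (s), non-negative.
#' @param peak_s response delay (gamma shape; mode at `peak_s - 1` s).
#' @param undershoot_s undershoot delay (gamma shape).
#' @param ratio undershoot-to-peak amplitude ratio.
#' @return Numeric vector of HRF values at `t`.
#' @export
hrf_double_gamma <- function(t, peak_s = 6, undershoot_s = 16, ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak_s, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot_s, rate = 1)
  h / max(abs(h))
}

#' fNIRS channel layout
#'
#' Sixteen channels in two parallel rows of eight across the forehead;
#' channels 1-8 cover the left, 9-16 the right prefrontal cortex.
#'
#' @return A tibble: `channel`, `hemisphere`, `row`, `position`.
#' @export
fnirs_channel_map <- function() {
  tibble::tibble(
    channel = 1:16,
    hemisphere = rep(c("left", "right"), each = 8),
    row = rep(1:2, each = 8),
    position = rep(1:8, times = 2)
  )
}

#' Generate a raw optical recording for one participant session
#'
#' Builds a serial trial timeline (10-s baseline, 7-s capture, then the
#' execution/report remainder of each trial period), injects
#' HRF-convolved oxygenation responses per hemisphere scaled so that the
#' capture-window mean oxy equals the ground-truth amplitude for the
#' trial's condition, converts concentrations to optical density through
#' the forward Beer-Lambert relation, and emits intensities
#' `I = I0 * 10^(-dOD)` with sinusoidal cardiac, respiratory and
#' Mayer-wave components plus white noise. Optional spike artifacts and
#' saturated channels exercise the motion-artifact rejection downstream.
#'
#' @param trials trial tibble for one participant, in presentation order.
#' @param truth a [ground_truth()].
#' @param config a [design_config()].
#' @param fs optical sampling rate (Hz).
#' @param constants an [mbll_constants()] (shared with the inverse).
#' @param noise list of noise amplitudes/frequencies; see [ground_truth()].
#'   Set amplitudes to 0 for a noise-free recording.
#' @param i0 resting intensity (ADC counts).
#' @param saturation_level ADC saturation ceiling.
#' @param saturate_channels channel indices pinned at saturation.
#' @param n_spikes number of motion-spike artifacts to inject at random
#'   times/channels.
#' @param spike_od optical-density amplitude of each spike.
#' @return An object of class `optical_recording`: sampling rate, time
#'   base, per-wavelength intensity matrices (time x channel), channel map,
#'   and event markers (`baseline_start`, `capture_start`, `capture_end`,
#'   `execution_start` per trial).
#' @export
generate_fnirs_session <- function(trials, truth, config,
                                   fs = config$fnirs_rate_hz,
                                   constants = mbll_constants(),
                                   noise = truth$fnirs_noise,
                                   i0 = 1000, saturation_level = 4095,
                                   saturate_channels = integer(0),
                                   n_spikes = 0, spike_od = 0.05) {
  conds <- unique(trials$condition)
  missing_amp <- setdiff(conds, colnames(truth$oxy_amplitude))
  abort_if(length(missing_amp) > 0,
           sprintf("oxy amplitude table missing condition(s): %s",
                   paste(missing_amp, collapse = ", ")))
  n_trials <- nrow(trials)
  per_trial <- round(config$trial_period_s * fs)
  n_t <- n_trials * per_trial
  t_s <- (seq_len(n_t) - 1) / fs

  trial_start <- (seq_len(n_trials) - 1) * per_trial  # 0-based sample offsets
  bl_len <- round(config$baseline_s * fs)
  cap_len <- round(config$capture_s * fs)
  cap_start <- trial_start + bl_len

  markers <- tibble::tibble(
    trial_id = rep(trials$trial_id, each = 4),
    event = rep(c("baseline_start", "capture_start", "capture_end",
                  "execution_start"), times = n_trials),
    t_s = as.vector(rbind(trial_start, cap_start, cap_start + cap_len,
                          cap_start + cap_len)) / fs
  )

  # Unit response: capture-window boxcar convolved with the HRF, rescaled so
  # its mean over the capture window is exactly 1.
  kernel <- hrf_double_gamma((seq_len(round(33 * fs)) - 1) / fs)
  unit <- stats::convolve(c(rep(1, cap_len), rep(0, length(kernel))),
                          rev(kernel), type = "open")[seq_len(cap_len + length(kernel))]
  unit <- unit / mean(unit[seq_len(cap_len)])

  hbo_scale <- 1 / (1 - truth$hbo_hhb_ratio)  # oxy = (1 - ratio) * HbO
  hemi_hbo <- matrix(0, n_t, 2, dimnames = list(NULL, c("left", "right")))
  for (h in c("left", "right")) {
    for (k in seq_len(n_trials)) {
      amp <- truth$oxy_amplitude[h, trials$condition[k]] * hbo_scale
      idx <- cap_start[k] + seq_along(unit)  # 1-based from capture onset
      keep <- idx <= n_t
      hemi_hbo[idx[keep], h] <- hemi_hbo[idx[keep], h] + amp * unit[keep]
    }
  }
  hemi_hhb <- truth$hbo_hhb_ratio * hemi_hbo

  channels <- fnirs_channel_map()
  wl <- as.character(constants$wavelengths)
  intensity <- list()
  for (w in seq_along(wl)) {
    od <- matrix(0, n_t, 16)
    for (ch in 1:16) {
      hemi <- channels$hemisphere[ch]
      od[, ch] <- mbll_forward_od(hemi_hbo[, hemi], hemi_hhb[, hemi],
                                  constants)[, w]
      if (noise$cardiac > 0) {
        od[, ch] <- od[, ch] + noise$cardiac *
          sin(2 * pi * noise$cardiac_hz * t_s + stats::runif(1, 0, 2 * pi))
      }
      if (noise$respiratory > 0) {
        od[, ch] <- od[, ch] + noise$respiratory *
          sin(2 * pi * noise$respiratory_hz * t_s + stats::runif(1, 0, 2 * pi))
      }
      if (noise$mayer > 0) {
        od[, ch] <- od[, ch] + noise$mayer *
          sin(2 * pi * noise$mayer_hz * t_s + stats::runif(1, 0, 2 * pi))
      }
      if (noise$white > 0) {
        od[, ch] <- od[, ch] + stats::rnorm(n_t, 0, noise$white)
      }
    }
    intensity[[wl[w]]] <- i0 * 10^(-od)
  }
  if (n_spikes > 0) {
    for (s in seq_len(n_spikes)) {
      ch <- sample(16, 1)
      at <- sample(n_t - 3, 1)
      for (w in wl) {
        intensity[[w]][at:(at + 2), ch] <-
          intensity[[w]][at:(at + 2), ch] * 10^(-spike_od)
      }
    }
  }
  for (ch in saturate_channels) {
    for (w in wl) intensity[[w]][, ch] <- saturation_level
  }
  structure(
    list(
      sampling_rate_hz = fs,
      t_s = t_s,
      intensity = intensity,
      channels = channels,
      markers = markers,
      i0 = i0,
      saturation_level = saturation_level,
      constants = constants
    ),
    class = "optical_recording"
  )
}

#' @export
print.optical_recording <- function(x, ...) {
  cat(sprintf(
    "<optical_recording: %d samples @ %g Hz, %d channels x %d wavelengths, %d trials>\n",
    length(x$t_s), x$sampling_rate_hz, ncol(x$intensity[[1]]),
    length(x$intensity), length(unique(x$markers$trial_id))))
  invisible(x)
}

#' Generate the optical sessions of a whole study
#'
#' One seeded [generate_fnirs_session()] per participant, with sub-seeds
#' derived deterministically from the global seed so any single session can
#' be regenerated in isolation.
#'
#' @param manifest trial tibble from [enumerate_design()].
#' @param truth a [ground_truth()].
#' @param config a [design_config()].
#' @param seed integer seed.
#' @param constants an [mbll_constants()].
#' @param ... further arguments to [generate_fnirs_session()].
#' @return A list of `optical_recording`s indexed by participant.
#' @export
generate_study_fnirs <- function(manifest, truth, config,
                                 seed = config$rng_seed,
                                 constants = mbll_constants(), ...) {
  lapply(seq_len(config$n_participants), function(p) {
    trials_p <- manifest[manifest$participant_id == p, , drop = FALSE]
    with_seed(derive_seed(seed, "fnirs", p),
              generate_fnirs_session(trials_p, truth, config,
                                     constants = constants, ...))
  })
}

#' Generate perceived-closeness (IOS) ratings
#'
#' One 1-7 rating per participant and rated condition, from a latent normal
#' discretized (rounded) and clamped to the scale ends. The pure MI
#' condition shows no model to relate to and is never rated.
#'
#' @param truth a [ground_truth()].
#' @param n_participants number of participants.
#' @param conditions conditions to rate (must not include `"MI"`).
#' @param seed integer seed.
#' @return A tibble: `participant_id`, `condition`, `rating`.
#' @export
generate_ios <- function(truth, n_participants,
                         conditions = names(truth$ios_latent_mean),
                         seed = 1L) {
  abort_if("MI" %in% conditions,
           "IOS ratings are not collected for the MI condition")
  missing <- setdiff(conditions, names(truth$ios_latent_mean))
  abort_if(length(missing) > 0,
           sprintf("no latent IOS mean for condition(s): %s",
                   paste(missing, collapse = ", ")))
  with_seed(derive_seed(seed, "ios"), {
    grid <- expand.grid(participant_id = seq_len(n_participants),
                        condition = conditions, stringsAsFactors = FALSE)
    latent <- stats::rnorm(nrow(grid),
                           truth$ios_latent_mean[grid$condition],
                           truth$ios_latent_sd)
    tibble::tibble(
      participant_id = as.integer(grid$participant_id),
      condition = grid$condition,
      rating = as.integer(pmin(7, pmax(1, round(latent))))
    )
  })
}
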