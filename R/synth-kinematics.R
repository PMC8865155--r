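# Synthetic movement kinematics: 3-D hand-position recordings whose
# principal-axis period carries a known, condition-dependent imitation bias.

#' Construct a kinematic recording object
#'
#' @param pos numeric matrix with columns `x`, `y`, `z`.
#' @param sampling_rate_hz sampling rate (Hz).
#' @param trial optional one-row trial specification carried along.
#' @param valid logical validity flag.
#' @param period_ms realized (noise-inclusive) movement period, if known.
#' @return An object of class `kinematic_recording`.
#' @keywords internal
new_kinematic_recording <- function(pos, sampling_rate_hz, trial = NULL,
                                    valid = TRUE, period_ms = NA_real_) {
  structure(
    list(
      t_s = (seq_len(nrow(pos)) - 1) / sampling_rate_hz,
      pos = pos,
      sampling_rate_hz = sampling_rate_hz,
      duration_s = nrow(pos) / sampling_rate_hz,
      trial = trial,
      valid = valid,
      period_ms = period_ms
    ),
    class = "kinematic_recording"
  )
}

#' @export
print.kinematic_recording <- function(x, ...) {
  cat(sprintf("<kinematic_recording: %d samples @ %.1f Hz (%.2f s)%s>\n",
              nrow(x$pos), x$sampling_rate_hz, x$duration_s,
              if (!x$valid) ", invalid" else ""))
  invisible(x)
}

#' Biased executed-movement period for one trial
#'
#' The tempo bias is multiplicative and symmetric on the log scale:
#' slow-distractor trials run at `base * sqrt(r)`, fast trials at
#' `base / sqrt(r)`, so the slow:fast cycle-time ratio equals `r` exactly,
#' independent of the participant's base tempo.
#'
#' @param base_ms participant's preferred cycle time (ms).
#' @param r condition bias ratio (> 0; 1 = no bias).
#' @param speed_label `"slow"` or `"fast"`.
#' @return Period in ms.
#' @export
biased_period_ms <- function(base_ms, r, speed_label) {
  abort_if(base_ms <= 0, "non-positive base tempo")
  abort_if(r <= 0, "bias ratio must be positive")
  if (speed_label == "slow") base_ms * sqrt(r) else base_ms / sqrt(r)
}

#' Generate one executed-movement recording
#'
#' The principal movement axis (z for vertical-plane actions, x for
#' horizontal) follows a sinusoid at the biased tempo, perturbed by a
#' per-trial lognormal tempo factor; all three axes carry Gaussian
#' measurement jitter. Invalid ("no action") trials contain slow postural
#' drift plus jitter and no rhythmical component, so downstream peak
#' detection finds nothing and the trial is discarded. Draws come from R's
#' global RNG stream, so the result is deterministic under `set.seed()`.
#'
#' @param trial one-row trial specification (as from [enumerate_block()]).
#' @param truth a [ground_truth()].
#' @param base_ms the participant's base cycle time (ms).
#' @param sampling_rate_hz sampling rate (Hz).
#' @param duration_s recording duration (s).
#' @param amplitude movement amplitude on the principal axis (position units).
#' @param tempo_sd_log per-trial lognormal tempo SD (overrides `truth`).
#' @param jitter_sd measurement noise SD (overrides `truth`).
#' @param invalid force an invalid no-action trial.
#' @return A `kinematic_recording`.
#' @export
generate_execution <- function(trial, truth, base_ms,
                               sampling_rate_hz = 103, duration_s = 4,
                               amplitude = 10,
                               tempo_sd_log = truth$tempo_sd_log,
                               jitter_sd = truth$jitter_sd,
                               invalid = FALSE) {
  abort_if(duration_s <= 0, "non-positive duration")
  r <- truth$bias_ratio[[trial$condition]]
  abort_if(is.null(r), sprintf("no bias ratio for condition '%s'", trial$condition))
  period <- biased_period_ms(base_ms, r, trial$speed_label)
  if (tempo_sd_log > 0) period <- period * exp(stats::rnorm(1, 0, tempo_sd_log))
  n <- round(sampling_rate_hz * duration_s)
  t <- (seq_len(n) - 1) / sampling_rate_hz
  pos <- matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  principal <- if (trial$plane == "vertical") "z" else "x"
  if (!invalid) {
    pos[, principal] <- amplitude * sin(2 * pi * t / (period / 1000))
  } else {
    # resting-hand drift dominating the amplitude range: no peak passes a
    # range-relative prominence gate
    pos[, principal] <- sample(c(-1, 1), 1) * 0.3 * amplitude *
      t / max(t)
  }
  if (jitter_sd > 0) {
    pos <- pos + matrix(stats::rnorm(3 * n, 0, jitter_sd), n, 3)
  }
  new_kinematic_recording(pos, sampling_rate_hz, trial = trial,
                          valid = !invalid,
                          period_ms = if (invalid) NA_real_ else period)
}

#' Generate a noise-free metronome-paced distractor trajectory
#'
#' One movement cycle per metronome beat on the principal axis, with the
#' default recording geometry of the kinematic system (4 s at 103 Hz).
#'
#' @param bpm metronome speed in beats per minute (> 0).
#' @param sampling_rate_hz sampling rate (Hz).
#' @param duration_s duration (s).
#' @param amplitude movement amplitude (position units).
#' @param plane `"vertical"` (z axis) or `"horizontal"` (x axis).
#' @return A `kinematic_recording` with period `60000 / bpm` ms.
#' @export
generate_distractor <- function(bpm, sampling_rate_hz = 103, duration_s = 4,
                                amplitude = 10, plane = "vertical") {
  abort_if(bpm <= 0, "bpm must be positive")
  period_ms <- 60000 / bpm
  n <- round(sampling_rate_hz * duration_s)
  t <- (seq_len(n) - 1) / sampling_rate_hz
  pos <- matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  principal <- if (plane == "vertical") "z" else "x"
  pos[, principal] <- amplitude * sin(2 * pi * t / (period_ms / 1000))
  new_kinematic_recording(pos, sampling_rate_hz, period_ms = period_ms)
}

#' Generate all executed-movement recordings for a study
#'
#' Walks the trial manifest in order, drawing per-trial tempo noise,
#' measurement jitter and invalid-trial indicators from a single seeded
#' stream. Warm-up trials are generated like any other (they are excluded
#' at the analysis stage, not here).
#'
#' @param manifest trial tibble from [enumerate_design()].
#' @param truth a [ground_truth()].
#' @param config a [design_config()].
#' @param seed integer seed.
#' @return A list with `recordings` (list indexed like `manifest` rows) and
#'   `base_ms` (per-participant base tempi).
#' @export
generate_study_kinematics <- function(manifest, truth, config,
                                      seed = config$rng_seed) {
  base_ms <- participant_base_tempi(truth, config$n_participants, seed = seed)
  recordings <- with_seed(derive_seed(seed, "kinematics"), {
    lapply(seq_len(nrow(manifest)), function(i) {
      tr <- manifest[i, ]
      invalid <- !tr$is_warmup && stats::runif(1) < truth$p_invalid
      generate_execution(tr, truth, base_ms[tr$participant_id],
                         sampling_rate_hz = config$sampling_rate_hz,
                         duration_s = config$duration_s,
                         invalid = invalid)
    })
  })
  list(recordings = recordings, base_ms = base_ms)
}
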