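# Experimental design: factorial trial enumeration for the four instruction
# conditions (AO, MI, AO+MI, intentional imitation), in blocks of 16 trials.

#' Study design configuration
#'
#' Describes the within-participant factorial design: four instruction
#' conditions manipulated across blocks, and within each block two action
#' types crossed with two movement planes, two distractor speeds, and (except
#' under pure motor imagery, which shows no distractor movie) the
#' compatibility between instructed and distractor action.
#'
#' @param n_participants number of participants.
#' @param conditions instruction-condition labels, in canonical order.
#' @param action_types two instructed pantomime actions.
#' @param planes two planes of motion; the vertical plane drives the z axis,
#'   the horizontal plane the x axis of the executed movement.
#' @param speeds_bpm named numeric, slow and fast distractor tempi in beats
#'   per minute. Cycle time in ms is `60000 / bpm`, so the default 60/90 bpm
#'   pair has a slow:fast stimulus ratio of 150%.
#' @param compatibility levels of instructed-vs-distractor action match.
#' @param trials_per_block analyzable trials per block; must equal
#'   `|actions| * |planes| * |speeds| * |compatibility|`.
#' @param n_catch_trials verbal-report (catch) trials per block in the three
#'   conditions that show a distractor movie; design metadata only.
#' @param sampling_rate_hz kinematic sampling rate (Hz).
#' @param duration_s kinematic recording duration per trial (s).
#' @param fnirs_rate_hz optical sampling rate of the fNIRS device (Hz).
#' @param baseline_s pre-trial fNIRS baseline duration (s).
#' @param capture_s fNIRS capture period per trial (s).
#' @param trial_period_s total fNIRS timeline allotted to one trial (s);
#'   must cover baseline + capture plus the execution/report interval.
#' @param rng_seed integer seed from which all stochastic draws derive.
#' @return An object of class `design_config` (a named list).
#' @export
design_config <- function(n_participants = 14L,
                          conditions = c("AO", "MI", "AO+MI", "IMIT"),
                          action_types = c("wash", "paint"),
                          planes = c("vertical", "horizontal"),
                          speeds_bpm = c(slow = 60, fast = 90),
                          compatibility = c("same", "different"),
                          trials_per_block = 16L,
                          n_catch_trials = 4L,
                          sampling_rate_hz = 103,
                          duration_s = 4,
                          fnirs_rate_hz = 2,
                          baseline_s = 10,
                          capture_s = 7,
                          trial_period_s = 40,
                          rng_seed = 1L) {
  n_cells <- length(action_types) * length(planes) * length(speeds_bpm) *
    length(compatibility)
  abort_if(trials_per_block != n_cells,
           sprintf("trials_per_block (%d) must equal the factorial cell count (%d)",
                   trials_per_block, n_cells))
  abort_if(is.null(names(speeds_bpm)) || !all(c("slow", "fast") %in% names(speeds_bpm)),
           "speeds_bpm must be named with 'slow' and 'fast'")
  abort_if(any(speeds_bpm <= 0), "distractor speeds must be positive")
  abort_if(trial_period_s < baseline_s + capture_s,
           "trial_period_s must cover baseline_s + capture_s")
  structure(
    list(
      n_participants = as.integer(n_participants),
      conditions = conditions,
      action_types = action_types,
      planes = planes,
      speeds_bpm = speeds_bpm,
      compatibility = compatibility,
      trials_per_block = as.integer(trials_per_block),
      n_catch_trials = as.integer(n_catch_trials),
      sampling_rate_hz = sampling_rate_hz,
      duration_s = duration_s,
      fnirs_rate_hz = fnirs_rate_hz,
      baseline_s = baseline_s,
      capture_s = capture_s,
      trial_period_s = trial_period_s,
      rng_seed = as.integer(rng_seed)
    ),
    class = "design_config"
  )
}

#' Ground truth for the synthetic study
#'
#' Known effect structure injected by the generators, against which the
#' pipeline's estimates are compared in parameter-recovery tests. The
#' default bias ratios and oxygenation amplitudes give the synthetic study
#' the effect ordering of the experimental paradigm it emulates: the
#' imitation bias grows from pure action observation through motor imagery
#' and combined AO+MI to intentional imitation, and the left prefrontal
#' oxygenation response is selectively raised under AO+MI.
#'
#' @param bias_ratio named numeric, one multiplicative tempo-bias ratio per
#'   condition (1 = no bias). Slow-distractor trials run at
#'   `base * sqrt(r)`, fast trials at `base / sqrt(r)`, so the extracted
#'   slow:fast ratio converges to `100 * r` percent.
#' @param base_cycle_time_mean_ms,base_cycle_time_sd_ms between-participant
#'   distribution of the preferred (unbiased) movement cycle time.
#' @param oxy_amplitude 2-row matrix (`left`, `right`) by condition: mean
#'   capture-window oxygenation response (oxy = HbO - HHb) in umol/L.
#' @param hbo_hhb_ratio injected `dHHb / dHbO` (typically negative).
#' @param ios_latent_mean named numeric, latent means of the 1-7 perceived
#'   closeness ratings per rated condition (MI is never rated).
#' @param ios_latent_sd latent SD of the closeness ratings.
#' @param tempo_sd_log per-trial lognormal tempo jitter (SD on the log scale).
#' @param jitter_sd kinematic measurement noise SD (position units).
#' @param p_invalid probability that a trial is an invalid response
#'   (no discernible action).
#' @param fnirs_noise list of optical noise amplitudes (optical-density
#'   units) and frequencies (Hz): `cardiac`, `respiratory`, `mayer`, `white`,
#'   `cardiac_hz`, `respiratory_hz`, `mayer_hz`.
#' @return An object of class `ground_truth` (a named list).
#' @export
ground_truth <- function(bias_ratio = c("AO" = 1.06, "MI" = 1.12,
                                        "AO+MI" = 1.18, "IMIT" = 1.33),
                         base_cycle_time_mean_ms = 890,
                         base_cycle_time_sd_ms = 70,
                         oxy_amplitude = rbind(
                           left  = c("AO" = 0.82, "MI" = 0.85,
                                     "AO+MI" = 1.48, "IMIT" = 1.04),
                           right = c("AO" = 0.99, "MI" = 1.04,
                                     "AO+MI" = 1.03, "IMIT" = 1.07)
                         ),
                         hbo_hhb_ratio = -0.3,
                         ios_latent_mean = c("AO" = 2.1, "AO+MI" = 2.9,
                                             "IMIT" = 4.3),
                         ios_latent_sd = 1.0,
                         tempo_sd_log = 0.05,
                         jitter_sd = 0.2,
                         p_invalid = 0.015,
                         fnirs_noise = list(
                           cardiac = 0.003, respiratory = 0.004,
                           mayer = 0.003, white = 0.002,
                           cardiac_hz = 1.1, respiratory_hz = 0.3,
                           mayer_hz = 0.1
                         )) {
  abort_if(any(bias_ratio <= 0), "bias ratios must be positive")
  abort_if(base_cycle_time_mean_ms <= 0, "base cycle time must be positive")
  abort_if(!is.matrix(oxy_amplitude) ||
             !all(rownames(oxy_amplitude) %in% c("left", "right")),
           "oxy_amplitude must be a matrix with rows 'left' and 'right'")
  structure(
    list(
      bias_ratio = bias_ratio,
      base_cycle_time_mean_ms = base_cycle_time_mean_ms,
      base_cycle_time_sd_ms = base_cycle_time_sd_ms,
      oxy_amplitude = oxy_amplitude,
      hbo_hhb_ratio = hbo_hhb_ratio,
      ios_latent_mean = ios_latent_mean,
      ios_latent_sd = ios_latent_sd,
      tempo_sd_log = tempo_sd_log,
      jitter_sd = jitter_sd,
      p_invalid = p_invalid,
      fnirs_noise = fnirs_noise
    ),
    class = "ground_truth"
  )
}

#' Enumerate the trials of one instruction block
#'
#' Returns the full factorial crossing for one block: action type x plane x
#' distractor speed x compatibility (16 analyzable trials with the default
#' design), preceded by a single warm-up trial that analyses exclude. Pure
#' motor imagery (MI) blocks show no distractor movie, so compatibility
#' cannot be manipulated there; a two-level repetition factor replaces it to
#' keep the trial count identical. Verbal-report catch trials are flagged in
#' the three movie conditions (none under MI) at seed-determined
#' pseudorandom positions; the flag is design metadata and does not remove a
#' trial from analysis.
#'
#' @param config a [design_config()].
#' @param condition one of `config$conditions`.
#' @param participant_id participant identifier (drives the catch-trial
#'   positions together with `config$rng_seed`).
#' @param block_index 0-based presentation index of the block.
#' @return A tibble of trial specifications; `trial_index` 0 is the warm-up,
#'   1..16 the analyzable trials.
#' @export
enumerate_block <- function(config, condition, participant_id = 1L,
                            block_index = 0L) {
  abort_if(!condition %in% config$conditions,
           sprintf("unknown condition label '%s'", condition))
  if (condition == "MI") {
    cells <- expand.grid(
      repetition = seq_len(length(config$compatibility)),
      speed_label = names(config$speeds_bpm),
      plane = config$planes,
      action_type = config$action_types,
      stringsAsFactors = FALSE
    )
    cells$compatibility <- NA_character_
  } else {
    cells <- expand.grid(
      compatibility = config$compatibility,
      speed_label = names(config$speeds_bpm),
      plane = config$planes,
      action_type = config$action_types,
      stringsAsFactors = FALSE
    )
    cells$repetition <- 1L
  }
  n <- nrow(cells)
  abort_if(n != config$trials_per_block,
           "factorial cells do not match trials_per_block")
  # Warm-up duplicates the first cell; excluded from analysis downstream.
  cells <- rbind(cells[1L, , drop = FALSE], cells)
  spec <- tibble::tibble(
    participant_id = as.integer(participant_id),
    condition = condition,
    action_type = cells$action_type,
    plane = cells$plane,
    speed_label = cells$speed_label,
    distractor_speed_bpm = unname(config$speeds_bpm[cells$speed_label]),
    compatibility = as.character(cells$compatibility),
    block_index = as.integer(block_index),
    trial_index = 0:n,
    is_warmup = c(TRUE, rep(FALSE, n)),
    catch_trial = FALSE,
    incorrect_action = FALSE
  )
  if (condition != "MI" && config$n_catch_trials > 0) {
    pos <- with_seed(
      derive_seed(config$rng_seed, "catch", participant_id, block_index),
      sample(seq_len(n), config$n_catch_trials)
    )
    spec$catch_trial[pos + 1L] <- TRUE  # offset past the warm-up row
  }
  spec
}

#' Enumerate the full study design
#'
#' One block per instruction condition and participant. AO is always
#' presented first (to keep that condition naive to imagery instructions)
#' and intentional imitation last (to keep participants naive to the speed
#' manipulation); the MI and AO+MI blocks are counterbalanced across
#' participants. Trial order within a block is a seed-determined
#' pseudorandom permutation of the factorial cells; `trial_index` is
#' reassigned to presentation order.
#'
#' @param config a [design_config()].
#' @return A tibble with one row per trial across all participants.
#' @export
enumerate_design <- function(config) {
  out <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    middle <- if (p %% 2L == 1L) c("MI", "AO+MI") else c("AO+MI", "MI")
    order_p <- c("AO", middle, "IMIT")
    order_p <- order_p[order_p %in% config$conditions]
    blocks <- vector("list", length(order_p))
    for (b in seq_along(order_p)) {
      blk <- enumerate_block(config, order_p[b], participant_id = p,
                             block_index = b - 1L)
      warm <- blk[blk$is_warmup, , drop = FALSE]
      main <- blk[!blk$is_warmup, , drop = FALSE]
      perm <- with_seed(derive_seed(config$rng_seed, "order", p, b - 1L),
                        sample(nrow(main)))
      main <- main[perm, , drop = FALSE]
      main$trial_index <- seq_len(nrow(main))
      blocks[[b]] <- rbind(warm, main)
    }
    out[[p]] <- do.call(rbind, blocks)
  }
  res <- do.call(rbind, out)
  res$trial_id <- seq_len(nrow(res))
  res
}

#' Per-participant preferred cycle times
#'
#' Draws each participant's unbiased base cycle time from the ground-truth
#' between-participant distribution, truncated away from implausibly fast
#' tempi.
#'
#' @param truth a [ground_truth()].
#' @param n_participants number of participants.
#' @param seed integer seed.
#' @return Numeric vector of base cycle times (ms), length `n_participants`.
#' @export
participant_base_tempi <- function(truth, n_participants, seed = 1L) {
  with_seed(derive_seed(seed, "base_tempo"), {
    b <- stats::rnorm(n_participants, truth$base_cycle_time_mean_ms,
                      truth$base_cycle_time_sd_ms)
    pmax(b, 300)
  })
}
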