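# Plain-text interchange formats: design JSON, trial manifest, per-trial
# kinematics CSVs, long-format optical CSVs, and rating tables.

#' Write and read the design/ground-truth configuration as JSON
#'
#' One JSON document holds the design configuration, the ground truth and
#' nothing else, so a run can be reproduced bit-exactly from the file plus
#' a seed.
#'
#' @param config a [design_config()].
#' @param truth a [ground_truth()].
#' @param path output path (`design.json` by convention).
#' @return `write_design_json()` returns `path` invisibly;
#'   `read_design_json()` returns `list(config, truth)`.
#' @export
write_design_json <- function(config, truth, path) {
  cfg <- unclass(config)
  tr <- unclass(truth)
  # named vectors as JSON objects so names survive the round trip
  cfg$speeds_bpm <- as.list(cfg$speeds_bpm)
  tr$bias_ratio <- as.list(tr$bias_ratio)
  tr$ios_latent_mean <- as.list(tr$ios_latent_mean)
  tr$oxy_amplitude <- list(left = as.list(tr$oxy_amplitude["left", ]),
                           right = as.list(tr$oxy_amplitude["right", ]))
  payload <- list(config = cfg, truth = tr)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", pretty = TRUE)
  invisible(path)
}

#' @rdname write_design_json
#' @export
read_design_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- raw$config
  config <- design_config(
    n_participants = cfg$n_participants,
    conditions = cfg$conditions,
    action_types = cfg$action_types,
    planes = cfg$planes,
    speeds_bpm = unlist(cfg$speeds_bpm),
    compatibility = cfg$compatibility,
    trials_per_block = cfg$trials_per_block,
    n_catch_trials = cfg$n_catch_trials,
    sampling_rate_hz = cfg$sampling_rate_hz,
    duration_s = cfg$duration_s,
    fnirs_rate_hz = cfg$fnirs_rate_hz,
    baseline_s = cfg$baseline_s,
    capture_s = cfg$capture_s,
    trial_period_s = cfg$trial_period_s,
    rng_seed = cfg$rng_seed
  )
  tr <- raw$truth
  amp <- rbind(left = unlist(tr$oxy_amplitude$left),
               right = unlist(tr$oxy_amplitude$right))
  truth <- ground_truth(
    bias_ratio = unlist(tr$bias_ratio),
    base_cycle_time_mean_ms = tr$base_cycle_time_mean_ms,
    base_cycle_time_sd_ms = tr$base_cycle_time_sd_ms,
    oxy_amplitude = amp,
    hbo_hhb_ratio = tr$hbo_hhb_ratio,
    ios_latent_mean = unlist(tr$ios_latent_mean),
    ios_latent_sd = tr$ios_latent_sd,
    tempo_sd_log = tr$tempo_sd_log,
    jitter_sd = tr$jitter_sd,
    p_invalid = tr$p_invalid,
    fnirs_noise = tr$fnirs_noise
  )
  list(config = config, truth = truth)
}

#' Write a trial manifest
#'
#' `trials.csv` with one row per trial; `block_index` is already 0-based
#' and `trial_index` 0 marks the warm-up trial of each block.
#'
#' @param manifest tibble from [enumerate_design()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write one kinematic recording as CSV
#'
#' Columns `t_s,x,y,z`, one file per trial.
#'
#' @param recording a `kinematic_recording`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_kinematics_csv <- function(recording, path) {
  df <- data.frame(t_s = recording$t_s, recording$pos, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kinematics_csv
#' @param sampling_rate_hz sampling rate to attach on read (inferred from
#'   the time column when omitted).
#' @export
read_kinematics_csv <- function(path, sampling_rate_hz = NULL) {
  df <- utils::read.csv(path)
  fs <- sampling_rate_hz %||% (1 / stats::median(diff(df$t_s)))
  new_kinematic_recording(as.matrix(df[, c("x", "y", "z")]), fs)
}

#' Write an optical recording as long CSV plus markers and channel map
#'
#' Three files: `optical.csv` (`t_s,channel,wavelength_nm,intensity` in
#' long format), `markers.csv` (`t_s,trial_id,event`) and `channels.csv`
#' (`channel,hemisphere,row,position`). An SNIRF export hook is reserved
#' as an extension point but not implemented.
#'
#' @param recording an `optical_recording`.
#' @param dir output directory.
#' @return The three file paths, invisibly.
#' @export
write_optical_csv <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wl <- names(recording$intensity)
  n_t <- length(recording$t_s)
  n_ch <- ncol(recording$intensity[[1]])
  long <- do.call(rbind, lapply(wl, function(w) {
    data.frame(
      t_s = rep(recording$t_s, times = n_ch),
      channel = rep(seq_len(n_ch), each = n_t),
      wavelength_nm = as.numeric(w),
      intensity = as.vector(recording$intensity[[w]])
    )
  }))
  paths <- file.path(dir, c("optical.csv", "markers.csv", "channels.csv"))
  utils::write.csv(long, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(recording$markers[, c("t_s", "trial_id", "event")],
                   paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(recording$channels, paths[3], row.names = FALSE,
                   quote = FALSE)
  invisible(paths)
}

#' @rdname write_optical_csv
#' @param i0 resting intensity to attach (metadata only).
#' @param saturation_level ADC ceiling to attach.
#' @param constants an [mbll_constants()] to attach.
#' @export
read_optical_csv <- function(dir, i0 = NA_real_, saturation_level = 4095,
                             constants = mbll_constants()) {
  long <- utils::read.csv(file.path(dir, "optical.csv"))
  markers <- tibble::as_tibble(utils::read.csv(file.path(dir, "markers.csv")))
  channels <- tibble::as_tibble(utils::read.csv(file.path(dir, "channels.csv")))
  t_s <- sort(unique(long$t_s))
  fs <- 1 / stats::median(diff(t_s))
  wl <- sort(unique(long$wavelength_nm))
  n_ch <- max(long$channel)
  intensity <- lapply(wl, function(w) {
    sub <- long[long$wavelength_nm == w, ]
    m <- matrix(NA_real_, length(t_s), n_ch)
    m[cbind(match(sub$t_s, t_s), sub$channel)] <- sub$intensity
    m
  })
  names(intensity) <- as.character(wl)
  structure(
    list(sampling_rate_hz = fs, t_s = t_s - t_s[1], intensity = intensity,
         channels = channels, markers = markers, i0 = i0,
         saturation_level = saturation_level, constants = constants),
    class = "optical_recording"
  )
}

#' Write Beer-Lambert constants as JSON
#'
#' Documents every constant (wavelengths, extinction matrix, DPF,
#' source-detector distance) for bit-exact reruns.
#'
#' @param constants an [mbll_constants()].
#' @param path output path (`mbll.json` by convention).
#' @return `path`, invisibly.
#' @export
write_mbll_json <- function(constants, path) {
  payload <- list(
    wavelengths = constants$wavelengths,
    extinction = list(
      HbO = unname(constants$extinction[, "HbO"]),
      HHb = unname(constants$extinction[, "HHb"])
    ),
    dpf = constants$dpf,
    distance_cm = constants$distance_cm,
    units = "extinction in 1/(mM cm); concentrations reported in umol/L"
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_mbll_json
#' @export
read_mbll_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  mbll_constants(
    wavelengths = raw$wavelengths,
    extinction = cbind(HbO = raw$extinction$HbO, HHb = raw$extinction$HHb),
    dpf = raw$dpf,
    distance_cm = raw$distance_cm
  )
}
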