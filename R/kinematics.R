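# Kinematic processing chain: zero-phase Butterworth smoothing, peak
# detection, windowed mean cycle time, invalid-trial filtering, and the
# slow:fast imitation-bias ratio.

#' Zero-phase Butterworth low-pass smoothing
#'
#' Second-order (by default) Butterworth low-pass applied bidirectionally
#' (forward and backward), giving zero phase distortion and an effective
#' magnitude response equal to the single-pass response squared. Edges are
#' stabilized by odd-reflection padding of three filter orders before the
#' forward-backward pass.
#'
#' @param series numeric vector.
#' @param sampling_rate_hz sampling rate (Hz).
#' @param cutoff_hz low-pass cutoff (Hz); must be below Nyquist.
#' @param order filter order of the single pass.
#' @return Filtered series, same length as the input.
#' @export
butterworth_smooth <- function(series, sampling_rate_hz, cutoff_hz = 6,
                               order = 2) {
  abort_if(cutoff_hz >= sampling_rate_hz / 2, "cutoff must be below Nyquist")
  abort_if(cutoff_hz <= 0, "cutoff must be positive")
  n <- length(series)
  pad <- 3L * order
  if (n < pad + 2L) {
    # too short for reflection padding: extend with edge values
    series2 <- c(rep(series[1], pad), series, rep(series[n], pad))
  } else {
    left <- 2 * series[1] - series[(pad + 1):2]
    right <- 2 * series[n] - series[(n - 1):(n - pad)]
    series2 <- c(left, series, right)
  }
  key <- sprintf("%d|%.12g", order, cutoff_hz / (sampling_rate_hz / 2))
  bf <- .butter_cache[[key]]
  if (is.null(bf)) {
    bf <- signal::butter(order, cutoff_hz / (sampling_rate_hz / 2),
                         type = "low")
    .butter_cache[[key]] <- bf
  }
  # steady-state initial conditions anchored at the first sample suppress
  # the start-up transient of the IIR recursion
  run <- function(x) {
    x0 <- x[1]
    y <- signal::filter(bf$b, bf$a, x - x0)
    unclass(y) + x0 * sum(bf$b) / sum(bf$a)
  }
  fwd <- run(series2)
  bwd <- rev(run(rev(fwd)))
  bwd[(pad + 1):(pad + n)]
}

.butter_cache <- new.env(parent = emptyenv())

# Prominence of a local maximum: height above the higher of the two minima
# separating it from the nearest higher ground (or the series edge).
peak_prominence <- function(series, idx) {
  n <- length(series)
  h <- series[idx]
  left_base <- right_base <- h
  i <- idx
  lo <- h
  while (i > 1) {
    i <- i - 1
    if (series[i] > h) break
    if (series[i] < lo) lo <- series[i]
  }
  left_base <- lo
  i <- idx
  lo <- h
  while (i < n) {
    i <- i + 1
    if (series[i] > h) break
    if (series[i] < lo) lo <- series[i]
  }
  right_base <- lo
  h - max(left_base, right_base)
}

#' Detect movement peaks
#'
#' Local maxima passing a minimum-prominence gate and a minimum-separation
#' gate. On a plateau of equal samples the earliest sample is taken. When
#' two candidates fall closer than `min_separation_ms`, the higher one is
#' kept (earlier on height ties).
#'
#' @param series filtered principal-axis series.
#' @param sampling_rate_hz sampling rate (Hz).
#' @param min_separation_ms minimum separation between retained peaks (ms).
#' @param min_prominence absolute prominence threshold; default 25% of the
#'   series' amplitude range.
#' @return Numeric vector of peak times (s), ascending; possibly empty.
#' @export
detect_peaks <- function(series, sampling_rate_hz, min_separation_ms = 300,
                         min_prominence = NULL) {
  abort_if(min_separation_ms <= 0, "min_separation_ms must be positive")
  n <- length(series)
  if (n < 3) return(numeric(0))
  if (is.null(min_prominence)) {
    min_prominence <- 0.25 * diff(range(series))
  }
  prev <- series[1:(n - 2)]
  cur <- series[2:(n - 1)]
  nxt <- series[3:n]
  cand <- which(cur > prev & cur >= nxt) + 1L
  if (length(cand) == 0) return(numeric(0))
  prom <- vapply(cand, function(i) peak_prominence(series, i), numeric(1))
  cand <- cand[prom >= min_prominence & prom > 0]
  if (length(cand) == 0) return(numeric(0))
  # separation gate: keep by descending height, earlier sample on ties
  ord <- order(-series[cand], cand)
  min_sep <- min_separation_ms / 1000 * sampling_rate_hz
  kept <- integer(0)
  for (i in cand[ord]) {
    if (all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  }
  sort((kept - 1L)) / sampling_rate_hz
}

#' Windowed mean cycle time
#'
#' Cycle times are the successive differences between peak positions inside
#' a half-open window anchored at the second detected peak (the first
#' movement cycle is excluded as potentially reflecting initial hand
#' positioning rather than stable rhythm). With the default 2-s window this
#' yields two to four complete cycles at 60-90 bpm tempi.
#'
#' @param peak_times ascending peak times (s).
#' @param window_s window length (s).
#' @param anchor `"second_peak"` (default) anchors the window at the second
#'   detected peak; `"onset"` anchors it at time 0 (alternative reading).
#' @return A list: `cycle_times_ms`, `mean_ms`, `window` (start, end),
#'   `valid`, `reason` (`NA` when valid).
#' @export
mean_cycle_time <- function(peak_times, window_s = 2.0,
                            anchor = c("second_peak", "onset")) {
  anchor <- match.arg(anchor)
  abort_if(is.unsorted(peak_times, strictly = TRUE) && length(peak_times) > 1,
           "peak_times must be strictly increasing")
  invalid <- function(reason) {
    list(cycle_times_ms = numeric(0), mean_ms = NA_real_,
         window = c(NA_real_, NA_real_), valid = FALSE, reason = reason)
  }
  if (length(peak_times) < 2) return(invalid("insufficient_peaks"))
  start <- if (anchor == "second_peak") peak_times[2] else 0
  window <- c(start, start + window_s)
  inside <- peak_times[peak_times >= window[1] & peak_times < window[2]]
  if (length(inside) < 2) return(invalid("insufficient_peaks_in_window"))
  ct <- diff(inside) * 1000
  list(cycle_times_ms = ct, mean_ms = mean(ct), window = window,
       valid = TRUE, reason = NA_character_)
}

#' Analyze one kinematic recording
#'
#' Full per-trial chain: principal-axis selection (maximum variance after
#' smoothing, or forced by plane), Butterworth smoothing, peak detection,
#' and windowed mean cycle time.
#'
#' @param recording a `kinematic_recording`.
#' @param cutoff_hz,order Butterworth parameters.
#' @param window_s cycle-time window (s).
#' @param min_separation_ms,min_prominence peak-detection gates.
#' @param axis optional axis override (`"x"`, `"y"`, `"z"`); default picks
#'   the smoothed axis with maximal variance.
#' @param anchor window anchoring, see [mean_cycle_time()].
#' @return A one-row tibble: peak count, cycle times, mean cycle time (ms),
#'   validity flag and reason.
#' @export
analyze_trial <- function(recording, cutoff_hz = 6, order = 2,
                          window_s = 2.0, min_separation_ms = 300,
                          min_prominence = NULL, axis = NULL,
                          anchor = "second_peak") {
  fs <- recording$sampling_rate_hz
  smoothed <- apply(recording$pos, 2, butterworth_smooth,
                    sampling_rate_hz = fs, cutoff_hz = cutoff_hz,
                    order = order)
  if (is.null(axis)) {
    axis <- colnames(smoothed)[which.max(apply(smoothed, 2, stats::var))]
  }
  series <- smoothed[, axis]
  peaks <- detect_peaks(series, fs, min_separation_ms = min_separation_ms,
                        min_prominence = min_prominence)
  mct <- mean_cycle_time(peaks, window_s = window_s, anchor = anchor)
  tibble::tibble(
    axis = axis,
    n_peaks = length(peaks),
    peak_times = list(peaks),
    cycle_times_ms = list(mct$cycle_times_ms),
    mean_cycle_time_ms = mct$mean_ms,
    valid = mct$valid,
    reason = mct$reason
  )
}

#' Analyze all trials of a study
#'
#' @param recordings list of `kinematic_recording`s, aligned with `manifest`
#'   rows.
#' @param manifest trial tibble from [enumerate_design()].
#' @param ... passed to [analyze_trial()].
#' @return `manifest` with the per-trial cycle analysis columns appended.
#' @export
analyze_kinematics <- function(recordings, manifest, ...) {
  res <- lapply(recordings, analyze_trial, ...)
  dplyr::bind_cols(manifest, dplyr::bind_rows(res))
}

#' Discard invalid trials
#'
#' A trial is invalid when no rhythmical action was produced (too few peaks
#' for a cycle-time estimate) or when the manifest flags an incorrect
#' executed action (which kinematics alone cannot detect). Warm-up trials
#' are not analyzable and are excluded from both the kept set and the
#' denominator.
#'
#' @param cycles tibble from [analyze_kinematics()].
#' @return A list: `kept`, `discarded`, `n_discarded`, `discard_percent`
#'   (one decimal, percent of analyzable trials).
#' @export
filter_invalid <- function(cycles) {
  analyzable <- cycles[!cycles$is_warmup, , drop = FALSE]
  bad <- !analyzable$valid | analyzable$incorrect_action
  kept <- analyzable[!bad, , drop = FALSE]
  discarded <- analyzable[bad, , drop = FALSE]
  pct <- if (nrow(analyzable) == 0) NA_real_ else
    round(100 * nrow(discarded) / nrow(analyzable), 1)
  list(kept = kept, discarded = discarded,
       n_discarded = nrow(discarded), discard_percent = pct)
}

#' Imitation-bias ratio per condition
#'
#' The imitation bias is `100 * mean(slow-trial cycle times) /
#' mean(fast-trial cycle times)` per participant and condition: 100% means
#' execution tempo ignored the distractor; values above 100% mean
#' executions drifted toward the observed tempi (the stimulus ratio itself
#' is 150%).
#'
#' @param kept tibble of valid analyzable trials (from [filter_invalid()]).
#' @param by_compatibility also split by compatibility (for the two-factor
#'   analysis; MI trials, which carry no compatibility, are dropped there).
#' @return A tibble per (participant, condition): mean slow and fast cycle
#'   times (ms), trial counts, and `bias_percent`; with
#'   `by_compatibility = TRUE`, additionally split by compatibility.
#' @export
imitation_bias <- function(kept, by_compatibility = FALSE) {
  groups <- c("participant_id", "condition",
              if (by_compatibility) "compatibility")
  df <- kept
  if (by_compatibility) df <- df[!is.na(df$compatibility), , drop = FALSE]
  agg <- dplyr::summarise(
    dplyr::group_by(df, dplyr::across(dplyr::all_of(groups)), .data$speed_label),
    mean_ct_ms = mean(.data$mean_cycle_time_ms),
    n_trials = dplyr::n(),
    .groups = "drop"
  )
  wide <- tidyr::pivot_wider(
    agg, names_from = "speed_label",
    values_from = c("mean_ct_ms", "n_trials")
  )
  missing_cell <- is.na(wide$mean_ct_ms_slow) | is.na(wide$mean_ct_ms_fast)
  if (any(missing_cell)) {
    warning(sprintf("%d condition cell(s) missing a speed; excluded",
                    sum(missing_cell)))
  }
  wide$bias_percent <- 100 * wide$mean_ct_ms_slow / wide$mean_ct_ms_fast
  dplyr::rename(wide,
                mean_ct_slow_ms = "mean_ct_ms_slow",
                mean_ct_fast_ms = "mean_ct_ms_fast",
                n_slow = "n_trials_slow", n_fast = "n_trials_fast")
}
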