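test_that("zero-phase Butterworth matches the analog magnitude oracle", {
  fs <- 103
  t <- (0:411) / fs
  # DC gain is 1
  expect_equal(butterworth_smooth(rep(3.7, 412), fs), rep(3.7, 412),
               tolerance = 1e-9)
  # |H|^2 of the order-2 analog prototype: (1 + (f/fc)^4)^-1
  H2 <- function(f, fc = 6) 1 / (1 + (f / fc)^4)
  for (f in c(1, 3)) {
    y <- butterworth_smooth(sin(2 * pi * f * t), fs)
    expect_equal(steady_amplitude(y), H2(f), tolerance = 0.02)
  }
  y20 <- butterworth_smooth(sin(2 * pi * 20 * t), fs)
  expect_lt(steady_amplitude(y20), 0.01)
  expect_error(butterworth_smooth(t, fs, cutoff_hz = 60), "Nyquist")
})

test_that("peak detection finds sinusoid peaks and survives noise", {
  fs <- 103
  t <- (0:411) / fs
  clean <- sin(2 * pi * t)  # 1000-ms period
  pk <- detect_peaks(clean, fs)
  expect_equal(length(pk), 4)
  expect_true(all(abs(diff(pk) * 1000 - 1000) <= 10))
  # flat series: no peaks
  expect_equal(detect_peaks(rep(1, 412), fs), numeric(0))
  # Gaussian noise at 5% amplitude with a 50%-amplitude prominence gate:
  # same peaks as the noise-free oracle, within one sample
  set.seed(42)
  for (rep in 1:5) {
    noisy <- clean + rnorm(412, 0, 0.05)
    pk_n <- detect_peaks(butterworth_smooth(noisy, fs), fs,
                         min_prominence = 0.5 * diff(range(noisy)) / 2)
    expect_equal(length(pk_n), length(pk))
    # residual noise on the flat sinusoid apex can move the argmax by a
    # few samples; 3 samples is ~3% of the period
    expect_true(all(abs(pk_n - pk) <= 3 / fs + 1e-12))
  }
})

test_that("peak ties break toward the earlier sample", {
  x <- c(0, 1, 1, 1, 0, 0)
  pk <- detect_peaks(x, 1, min_separation_ms = 500, min_prominence = 0.5)
  expect_equal(pk, 1)  # sample 2, time (2-1)/1
})

test_that("windowed mean cycle time follows the second-peak anchor", {
  # uniform 1-s spacing: window [1.5, 3.5), included peaks {1.5, 2.5}
  res <- mean_cycle_time(c(0.5, 1.5, 2.5, 3.5))
  expect_equal(res$window, c(1.5, 3.5))
  expect_equal(res$cycle_times_ms, 1000)
  expect_equal(res$mean_ms, 1000)
  expect_true(res$valid)
  # 90-bpm spacing
  p90 <- 60 / 90 * (0:5) + 0.1
  expect_equal(mean_cycle_time(p90)$mean_ms, 60000 / 90, tolerance = 1e-9)
  # degenerate inputs are flagged, not raised
  expect_false(mean_cycle_time(numeric(0))$valid)
  one <- mean_cycle_time(1.0)
  expect_false(one$valid)
  expect_equal(one$reason, "insufficient_peaks")
  # two peaks further apart than the window: none besides the anchor inside
  sparse <- mean_cycle_time(c(0.2, 0.5, 3.9))
  expect_false(sparse$valid)
  expect_equal(sparse$reason, "insufficient_peaks_in_window")
})

test_that("windowed mean cycle time equals brute-force enumeration", {
  # property: on integer-spaced synthetic peak lists the windowed mean
  # matches an independent enumeration of in-window successive differences
  brute <- function(p, w = 2) {
    if (length(p) < 2) return(NA_real_)
    lo <- p[2]; hi <- p[2] + w
    inside <- p[p >= lo & p < hi]
    if (length(inside) < 2) return(NA_real_)
    mean(diff(inside)) * 1000
  }
  set.seed(7)
  for (i in 1:50) {
    gaps <- sample(3:11, sample(2:8, 1), replace = TRUE) / 10
    p <- cumsum(c(runif(1), gaps))
    res <- mean_cycle_time(p)
    expect_equal(res$mean_ms, brute(p), tolerance = 1e-12)
  }
})

test_that("invalid-trial filtering reproduces the discard arithmetic", {
  make_cycles <- function(n, n_bad_nopeak = 0, n_bad_incorrect = 0) {
    tibble::tibble(
      is_warmup = FALSE,
      valid = c(rep(FALSE, n_bad_nopeak), rep(TRUE, n - n_bad_nopeak)),
      incorrect_action = c(rep(FALSE, n - n_bad_incorrect),
                           rep(TRUE, n_bad_incorrect)),
      mean_cycle_time_ms = 800
    )
  }
  # the study's design: 14 participants x 4 blocks x 16 trials, 13 invalid
  f <- filter_invalid(make_cycles(896, n_bad_nopeak = 13))
  expect_equal(f$discard_percent, 1.5)
  expect_equal(nrow(f$kept), 883)
  # no invalid trials
  f0 <- filter_invalid(make_cycles(100))
  expect_equal(f0$discard_percent, 0.0)
  expect_equal(nrow(f0$kept), 100)
  # all invalid: empty kept set without error
  fa <- filter_invalid(make_cycles(10, n_bad_nopeak = 10))
  expect_equal(fa$discard_percent, 100.0)
  expect_equal(nrow(fa$kept), 0)
  # warm-ups count in neither numerator nor denominator
  cyc <- make_cycles(20, n_bad_nopeak = 1)
  cyc$is_warmup[15] <- TRUE
  expect_equal(filter_invalid(cyc)$discard_percent, round(100 / 19, 1))
})

test_that("imitation bias is the slow:fast cycle-time percentage", {
  base <- tibble::tibble(
    participant_id = 1L, condition = "AO",
    compatibility = rep(c("same", "different"), 8),
    speed_label = rep(c("slow", "fast"), each = 8),
    mean_cycle_time_ms = 800
  )
  # equal tempi in both speeds: exactly 100%
  expect_equal(imitation_bias(base)$bias_percent, 100)
  # stimulus-ratio means: 150%
  b <- base
  b$mean_cycle_time_ms <- ifelse(b$speed_label == "slow", 1000, 60000 / 90)
  expect_equal(imitation_bias(b)$bias_percent, 150, tolerance = 1e-9)
  # realistic unequal grand means: 980 / 813 -> 120.5%
  b$mean_cycle_time_ms <- ifelse(b$speed_label == "slow", 980, 813)
  expect_equal(imitation_bias(b)$bias_percent, 100 * 980 / 813,
               tolerance = 1e-12)
  # compatibility split keeps both cells
  bc <- imitation_bias(base, by_compatibility = TRUE)
  expect_equal(nrow(bc), 2)
  expect_equal(bc$bias_percent, c(100, 100))
})

test_that("cycle extraction is scale-invariant and tempo-equivariant", {
  truth <- truth_noise_free()
  tr <- enumerate_block(small_config(), "AO")[2, ]
  rec <- generate_execution(tr, truth, base_ms = 850)
  res1 <- analyze_trial(rec)
  # scaling all amplitudes leaves peak times and cycle times unchanged
  rec_scaled <- rec
  rec_scaled$pos <- rec$pos * 37.5
  res2 <- analyze_trial(rec_scaled)
  expect_equal(res1$peak_times[[1]], res2$peak_times[[1]])
  expect_equal(res1$mean_cycle_time_ms, res2$mean_cycle_time_ms)
  # halving the sampling rate (time rescale k = 2 on the same samples)
  # doubles the mean cycle time
  rec_slow <- rec
  rec_slow$sampling_rate_hz <- rec$sampling_rate_hz / 2
  res3 <- analyze_trial(rec_slow, window_s = 4)
  expect_equal(res3$mean_cycle_time_ms, 2 * res1$mean_cycle_time_ms,
               tolerance = 1e-9)
})

test_that("injected bias ratios are recovered from noisy recordings", {
  # reduced-size recovery check (the full Monte-Carlo lives in the
  # acceptance suite): 60 replicate condition-blocks at r = 1.18
  truth <- ground_truth(bias_ratio = c("AO" = 1.18, "MI" = 1.18,
                                       "AO+MI" = 1.18, "IMIT" = 1.18))
  cfg <- small_config()
  blk <- enumerate_block(cfg, "AO")
  main <- blk[!blk$is_warmup, ]
  set.seed(31)
  est <- replicate(60, {
    recs <- lapply(seq_len(nrow(main)), function(i) {
      generate_execution(main[i, ], truth, base_ms = 890)
    })
    cyc <- analyze_kinematics(recs, main)
    imitation_bias(filter_invalid(cyc)$kept)$bias_percent
  })
  expect_equal(mean(est), 118, tolerance = 0.02)
})
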