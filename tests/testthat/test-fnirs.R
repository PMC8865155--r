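test_that("FIR low-pass has unit DC gain and the windowed-sinc response", {
  fs <- 10
  t <- (0:2999) / fs
  expect_equal(fir_lowpass(rep(2.5, 300), fs), rep(2.5, 300),
               tolerance = 1e-9)
  # analytic response of the tap vector (independent of the time-domain
  # convolution route used by the filter itself)
  taps <- signal::fir1(50, 0.1 / (fs / 2), type = "low")
  taps <- taps / sum(taps)
  H <- function(f) abs(sum(taps * exp(-2i * pi * f / fs * (0:50))))
  # 1.1-Hz cardiac component attenuated below 5% with cutoff 0.1 Hz
  y <- fir_lowpass(sin(2 * pi * 1.1 * t), fs, cutoff_hz = 0.1)
  expect_lt(steady_amplitude(y), 0.05)
  expect_equal(steady_amplitude(y), H(1.1), tolerance = 0.01)
  # 0.01-Hz component preserved within 2%
  t_long <- (0:7999) / fs
  y2 <- fir_lowpass(sin(2 * pi * 0.01 * t_long), fs, cutoff_hz = 0.1)
  expect_equal(steady_amplitude(y2), 1, tolerance = 0.02)
  expect_gt(H(0.01), 0.99)
  # group delay is compensated: a passband sinusoid comes back aligned
  # (an uncompensated 25-tap delay would shift the phase by ~0.8 rad here)
  x <- sin(2 * pi * 0.01 * t_long)
  y3 <- fir_lowpass(x, fs, cutoff_hz = 0.2)
  core <- 100:7900  # away from the reflection-padded edges
  expect_lt(max(abs(y3[core] - x[core])), 0.02)
  expect_error(fir_lowpass(t, fs, cutoff_hz = 6), "Nyquist")
  expect_error(fir_lowpass(t, fs, n_taps = 50), "odd")
})

make_recording <- function(n_t = 400, fs = 2, n_ch = 4, i0 = 1000,
                           sat = 4095) {
  set.seed(99)
  intensity <- lapply(1:2, function(w) {
    matrix(i0 + rnorm(n_t * n_ch, 0, 5), n_t, n_ch)
  })
  names(intensity) <- c("730", "850")
  structure(
    list(sampling_rate_hz = fs, t_s = (0:(n_t - 1)) / fs,
         intensity = intensity,
         channels = fnirs_channel_map()[1:n_ch, ],
         markers = tibble::tibble(trial_id = integer(0),
                                  event = character(0), t_s = numeric(0)),
         i0 = i0, saturation_level = sat, constants = mbll_constants()),
    class = "optical_recording"
  )
}

test_that("SMAR rejects saturated channels and variance spikes only", {
  rec <- make_recording()
  # clean low-variance channels: everything accepted
  m0 <- smar_mask(rec)
  expect_true(all(m0$accept))
  # channel pinned at saturation: all its windows rejected
  rec_sat <- rec
  rec_sat$intensity[["730"]][, 2] <- rec$saturation_level
  m1 <- smar_mask(rec_sat)
  expect_true(all(!m1$accept[, 2]))
  expect_true(all(m1$accept[, -2]))
  # one 10x-SD spike: exactly the overlapping windows rejected
  rec_spk <- rec
  spike_at <- 101  # inside window 6 (samples 101-120 at 10 s x 2 Hz)
  rec_spk$intensity[["850"]][spike_at, 3] <-
    rec_spk$intensity[["850"]][spike_at, 3] + 10 * 5 * sqrt(20)
  m2 <- smar_mask(rec_spk)
  hit <- which(m2$window_start <= spike_at & m2$window_end >= spike_at)
  expect_false(any(m2$accept[hit, 3]))
  expect_true(all(m2$accept[-hit, 3]))
  expect_true(all(m2$accept[, -3]))
  # rejection never alters accepted samples, only membership
  expect_equal(sum(!m2$sample_accept[, 3]),
               m2$window_end[hit] - m2$window_start[hit] + 1)
})

test_that("the Beer-Lambert inversion recovers forward-model inputs", {
  const <- mbll_constants()
  n <- 60
  hbo <- c(rep(0, 10), rep(1.0, n - 10))
  hhb <- c(rep(0, 10), rep(-0.3, n - 10))
  od <- simbias:::mbll_forward_od(hbo, hhb, const)
  intensity <- lapply(1:2, function(w) matrix(1000 * 10^(-od[, w]), ncol = 1))
  h <- mbll(intensity, baseline_idx = 1:10, constants = const)
  expect_equal(h$hbo[n, 1], 1.0, tolerance = 1e-9)
  expect_equal(h$hhb[n, 1], -0.3, tolerance = 1e-9)
  expect_equal(h$oxy[n, 1], 1.3, tolerance = 1e-9)
  expect_equal(h$thb[n, 1], 0.7, tolerance = 1e-9)
  # identical intensities to baseline: all change scores zero
  flat <- lapply(1:2, function(w) matrix(500, 40, 2))
  h0 <- mbll(flat, 1:10, const)
  expect_true(all(abs(h0$hbo) < 1e-12) && all(abs(h0$oxy) < 1e-12))
  # compound scores are exact sums/differences at every sample
  expect_equal(h$thb, h$hbo + h$hhb)
  expect_equal(h$oxy, h$hbo - h$hhb)
})

test_that("compound scores follow their definitions", {
  const <- mbll_constants()
  od <- simbias:::mbll_forward_od(rep(0.8, 20), rep(0.8, 20), const)
  intensity <- lapply(1:2, function(w) {
    matrix(c(rep(1000, 10), 1000 * 10^(-od[11:20, w])), ncol = 1)
  })
  h <- mbll(intensity, 1:10, const)
  expect_equal(h$thb[20, 1], 1.6, tolerance = 1e-9)
  expect_equal(h$oxy[20, 1], 0.0, tolerance = 1e-9)
})

test_that("MBLL is linear in optical density and baseline-invariant", {
  const <- mbll_constants()
  set.seed(5)
  # exactly-zero baseline so the baseline intensity is constant and dOD is
  # the forward od itself
  hbo <- c(rep(0, 10), cumsum(rnorm(40, 0, 0.1)))
  hhb <- c(rep(0, 10), cumsum(rnorm(40, 0, 0.05)))
  od <- simbias:::mbll_forward_od(hbo, hhb, const)
  to_int <- function(od, i0) lapply(1:2, function(w) {
    matrix(i0 * 10^(-od[, w]), ncol = 1)
  })
  h1 <- mbll(to_int(od, 1000), 1:10, const)
  h2 <- mbll(to_int(2 * od, 1000), 1:10, const)
  expect_equal(h2$hbo, 2 * h1$hbo, tolerance = 1e-6)
  expect_equal(h2$oxy, 2 * h1$oxy, tolerance = 1e-6)
  # multiplying I and I0 by any positive constant changes nothing
  h3 <- mbll(to_int(od, 12345.6), 1:10, const)
  expect_equal(h3$hbo, h1$hbo, tolerance = 1e-9)
  # error contracts
  bad <- to_int(od, 1000); bad[[1]][20, 1] <- -1
  expect_error(mbll(bad, 1:10, const), "non-positive")
  expect_error(
    mbll_constants(extinction = rbind(c(HbO = 1, HHb = 1),
                                      c(HbO = 1, HHb = 1))),
    "singular")
})

test_that("capture segmentation takes mask-aware window means", {
  fs <- 2
  n_t <- 60
  markers <- tibble::tibble(
    trial_id = c(1L, 1L, 1L, 1L),
    event = c("baseline_start", "capture_start", "capture_end",
              "execution_start"),
    t_s = c(0, 10, 17, 17)
  )
  hemo <- structure(list(
    hbo = matrix(2, n_t, 2), hhb = matrix(-1, n_t, 2),
    thb = matrix(1, n_t, 2), oxy = matrix(3, n_t, 2)
  ), class = "hemodynamic_series")
  # constant c during the window, zero baseline reference offsets
  hemo0 <- hemo
  for (m in c("hbo", "hhb", "thb", "oxy")) hemo0[[m]][1:20, ] <- 0
  seg <- segment_capture(hemo0, markers, fs)
  expect_equal(seg$oxy, c(3, 3))
  expect_equal(seg$n_accepted, c(14L, 14L))
  # half the window rejected, remainder constant: mean unchanged
  acc <- matrix(TRUE, n_t, 2); acc[21:27, 1] <- FALSE
  seg2 <- segment_capture(hemo0, markers, fs, sample_accept = acc)
  expect_equal(seg2$oxy[1], 3)
  expect_equal(seg2$n_accepted[1], 7L)
  # ramp 0 -> 1 over the window averages to ~0.5
  hemo_r <- hemo0
  hemo_r$oxy[, ] <- 0
  hemo_r$oxy[21:34, ] <- seq(0, 1, length.out = 14)
  seg3 <- segment_capture(hemo_r, markers, fs)
  expect_equal(seg3$oxy[1], 0.5, tolerance = 1 / 14)
  # fully rejected channel flagged missing, not an error
  acc_all <- matrix(TRUE, n_t, 2); acc_all[21:34, 2] <- FALSE
  seg4 <- segment_capture(hemo0, markers, fs, sample_accept = acc_all)
  expect_true(is.na(seg4$oxy[2]))
})

test_that("condition table averages trials then channels per hemisphere", {
  man <- tibble::tibble(
    trial_id = 1:4, participant_id = 1L,
    condition = c("AO", "AO", "AO+MI", "AO+MI"),
    is_warmup = FALSE
  )
  tm <- tidyr::expand_grid(trial_id = 1:4, channel = 1:16)
  tm$oxy <- ifelse(man$condition[tm$trial_id] == "AO+MI" & tm$channel <= 8,
                   1.26, 0.9)
  tm$hbo <- tm$oxy / 1.3
  tm$hhb <- -0.3 * tm$hbo
  tab <- condition_oxy(tm, man, fnirs_channel_map())
  left_aomi <- tab[tab$condition == "AO+MI" & tab$hemisphere == "left", ]
  expect_equal(left_aomi$oxy, 1.26)
  expect_equal(left_aomi$oxy_change, 1.26 - 0.9)
  expect_true(all(tab$oxy_change[tab$condition == "AO"] == 0))
  # identical means everywhere: all change scores zero
  tm$oxy <- 0.7; tm$hbo <- 0.7 / 1.3; tm$hhb <- -0.3 * tm$hbo
  tab2 <- condition_oxy(tm, man, fnirs_channel_map())
  expect_true(all(abs(tab2$oxy_change) < 1e-12))
  expect_true(all(tab2$oxy == 0.7))
})

test_that("rejecting more windows never changes accepted-sample values", {
  rec <- make_recording(n_t = 200)
  markers <- tibble::tibble(
    trial_id = c(1L, 1L, 1L, 1L),
    event = c("baseline_start", "capture_start", "capture_end",
              "execution_start"),
    t_s = c(0, 10, 17, 17)
  )
  rec$markers <- markers
  const <- mbll_constants()
  h <- mbll(rec$intensity, 1:20, const)
  acc <- matrix(TRUE, 200, 4)
  acc[30:40, 2] <- FALSE
  h2 <- mbll(rec$intensity, 1:20, const, sample_accept = acc)
  expect_equal(h2$oxy[acc[, 2], 2], h$oxy[acc[, 2], 2])
  expect_true(all(is.na(h2$oxy[!acc[, 2], 2])))
})
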