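# Filtering, downsampling, epoching and sliding-window extraction.

make_rec <- function(x, fs, events = data.frame(onset = numeric(),
                                                condition = character())) {
  eeg_recording(matrix(x, nrow = 1), fs = fs, channels = "C3",
                events = events)
}

test_that("band-pass keeps in-band content and removes DC", {
  fs <- 128
  x10 <- sine_wave(10, fs, 30)
  rec <- bandpass_filter(make_rec(x10, fs))
  mid <- (5 * fs):(25 * fs)
  expect_lt(max(abs(rec$signal[1, mid] - x10[mid])), 0.01)

  # DC-only input is wiped by the 0.5 Hz high-pass edge
  recdc <- bandpass_filter(make_rec(rep(7, 30 * fs), fs))
  expect_lt(max(abs(recdc$signal[1, mid])), 0.05)

  expect_error(bandpass_filter(make_rec(x10, fs), low = 0.5, high = 70),
               "fs/2")
})

test_that("out-of-band attenuation matches the filter's own squared response", {
  # analytic two-pass Butterworth magnitude at 60 Hz (fs = 1024):
  # |H|^2 with |H| = 1/sqrt(1 + (60/45)^(2*4)) gives ~0.09, and the
  # designed (prewarped) digital filter is the reference the output must
  # match
  fs <- 1024
  x60 <- sine_wave(60, fs, 10)
  rec <- bandpass_filter(make_rec(x60, fs))
  mid <- (3 * fs):(7 * fs)
  ratio <- sd(rec$signal[1, mid]) / sd(x60[mid])
  analog2 <- 1 / (1 + (60 / 45)^8)
  expect_lt(abs(ratio - analog2), 0.02)
  expect_lt(ratio, 0.12)
})

test_that("filtering is zero-phase and idempotent in band", {
  fs <- 128
  x10 <- sine_wave(10, fs, 30)
  rec1 <- bandpass_filter(make_rec(x10, fs))
  rec2 <- bandpass_filter(rec1)
  mid <- (5 * fs):(25 * fs)
  # double application changes in-band RMS by < 2%
  expect_lt(abs(sd(rec2$signal[1, mid]) / sd(rec1$signal[1, mid]) - 1), 0.02)
  # cross-correlation peak at lag 0 (no phase shift)
  cc <- ccf(rec1$signal[1, mid], x10[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("notch removes the mains line and nothing else", {
  fs <- 128
  mid <- (5 * fs):(25 * fs)
  x50 <- sine_wave(50, fs, 30)
  rec <- notch_filter(make_rec(x50, fs))
  expect_lt(sd(rec$signal[1, mid]) / sd(x50[mid]), 0.05)

  x10 <- sine_wave(10, fs, 30)
  rec10 <- notch_filter(make_rec(x10, fs))
  expect_lt(max(abs(rec10$signal[1, mid] - x10[mid])), 0.01)

  silence <- notch_filter(make_rec(rep(0, 30 * fs), fs))
  expect_equal(max(abs(silence$signal)), 0)
  expect_error(notch_filter(make_rec(x10, fs), freq = 70), "Nyquist")
})

test_that("downsampling preserves spectral peaks and event times", {
  fs <- 1024
  ev <- data.frame(onset = 3.000, condition = "right")
  rec <- make_rec(sine_wave(10, fs, 8), fs, events = ev)
  dn <- downsample(rec, 128)
  expect_equal(dn$fs, 128)
  expect_equal(ncol(dn$signal), 8 * 128)      # ratio 8
  expect_equal(dn$events$onset, 3.000)        # seconds-based events

  P <- Mod(fft(dn$signal[1, ]))^2
  f <- (seq_along(P) - 1) * 128 / length(P)
  expect_equal(f[which.max(P[f <= 64])], 10, tolerance = 0.01)

  expect_error(downsample(rec, 2048), "below")
  expect_error(downsample(rec, 100), "divide")
})

test_that("epoching produces onset-locked 6 s trials and drops edge events", {
  fs <- 128
  ev <- data.frame(onset = c(5, 1, 10), condition = c("right", "left", "rest"))
  rec <- make_rec(rnorm(15 * fs), fs, events = ev)
  expect_warning(ts <- epoch_trials(rec), "dropped")
  expect_equal(dim(ts$data), c(2L, 1L, 768L))   # 6 s x 128 Hz
  expect_equal(ts$condition, c("right", "rest"))
  expect_equal(range(ts$time), c(-3, 3 - 1 / fs))

  # onset-locking: a delta at the event lands at t = 0
  sig <- rep(0, 15 * fs); sig[5 * fs + 1] <- 1
  rec2 <- make_rec(sig, fs, events = data.frame(onset = 5, condition = "x"))
  ts2 <- epoch_trials(rec2)
  expect_equal(ts2$time[which.max(ts2$data[1, 1, ])], 0)

  empty <- epoch_trials(make_rec(rnorm(10 * fs), fs))
  expect_equal(dim(empty$data)[1], 0L)
})

test_that("sliding windows are causal, 100 ms stepped, fully covering", {
  fs <- 128
  ws <- sliding_windows(rnorm(6 * fs), fs, t_start = -3)
  expect_equal(nrow(ws$data), 41L)
  expect_equal(ws$t, seq(-1, 3, by = 0.1))
  expect_equal(ncol(ws$data), 256L)

  # consecutive windows overlap by 1.9 s; union covers the trial
  x <- seq_len(6 * fs)
  wsx <- sliding_windows(x, fs, t_start = -3)
  expect_equal(sum(wsx$data[2, ] %in% wsx$data[1, ]) / fs, 1.9, tolerance = 0.01)
  expect_equal(sort(unique(as.vector(wsx$data))), x)

  expect_equal(nrow(sliding_windows(rnorm(2 * fs), fs)$data), 1L)
  ws2 <- sliding_windows(rnorm(4 * fs), fs, step_s = 2)
  expect_equal(nrow(ws2$data), 2L)
  expect_error(sliding_windows(rnorm(100), fs), "shorter")
})
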