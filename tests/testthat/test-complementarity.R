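# Ablations (ERD suppression, LRTC removal), Mann-Whitney masks, and
# ERD-LRTC lag analysis.

test_that("suppress_erd fixes in-band magnitudes and touches nothing else", {
  fs <- 128
  set.seed(101)
  ws <- sliding_windows(rnorm(6 * fs), fs, t_start = -3)
  out <- suppress_erd(ws, seed = 5)
  donor <- attr(out, "donor")
  N <- ncol(ws$data)
  freq <- (seq_len(N) - 1) * fs / N
  inband <- freq >= 8 & freq <= 13 & freq <= fs / 2
  expect_equal(sum(inband), 11L)   # 0.5 Hz resolution: bins 8, 8.5 ... 13

  mag_d <- Mod(fft(out$data[donor, ]))[inband]
  for (i in seq_len(nrow(out$data))) {
    X0 <- fft(ws$data[i, ]); X1 <- fft(out$data[i, ])
    # in-band magnitudes bitwise-equal to the donor's
    expect_equal(Mod(X1)[inband], mag_d, tolerance = 1e-12)
    # phases kept
    expect_equal(Arg(X1)[inband][mag_d > 0], Arg(X0)[inband][mag_d > 0],
                 tolerance = 1e-6)
    # out-of-band bins untouched (positive freqs, excluding mirror band)
    outband <- freq < 8 & freq > 0 & freq < fs / 2
    expect_equal(X1[outband], X0[outband], tolerance = 1e-10)
  }
  # output real: max imaginary residue tiny relative to signal RMS
  X <- fft(out$data[1, ])
  rec <- fft(X, inverse = TRUE) / N
  expect_lt(max(abs(Im(rec))) / sd(out$data[1, ]), 1e-10)

  # donor window itself is unchanged
  expect_equal(out$data[donor, ], ws$data[donor, ], tolerance = 1e-12)
  expect_error(suppress_erd(ws$data[1, , drop = FALSE], fs = fs), "at least 2")
})

test_that("suppress_erd flattens the ERD trace on synthetic movement data", {
  cfg <- synthetic_config(n_trials_per_condition = 4, alpha_amplitude = 4,
                          seed = 102)
  ds <- synthesize_movement_dataset(cfg)
  tr <- epoch_trials(ds[[1]]$recording)
  mv <- which(tr$condition == "right")
  var_orig <- var_supp <- numeric(0)
  for (i in mv) {
    ws <- sliding_windows(tr$data[i, 1, ], tr$fs, t_start = -3)
    bp0 <- apply(ws$data, 1, alpha_band_power, fs = tr$fs)
    sup <- suppress_erd(ws, seed = 103 + i)
    bp1 <- apply(sup$data, 1, alpha_band_power, fs = tr$fs)
    var_orig <- c(var_orig, var(bp0 / mean(bp0)))
    var_supp <- c(var_supp, var(bp1 / mean(bp1)))
  }
  expect_lt(mean(var_supp) / mean(var_orig), 0.1)  # >= 90% variance removed
})

test_that("remove_lrtc drives the Hurst exponent back to 0.5", {
  hs <- numeric(30)
  for (i in 1:30) {
    x <- simulate_arfima(d = 0.3, n_samples = 256, seed = case_seed(104, i))
    y <- remove_lrtc(matrix(x, nrow = 1))
    hs[i] <- estimate_hurst(y[1, ])$H
  }
  expect_lt(abs(mean(hs) - 0.5), 0.07)
})

test_that("compare_conditions is calibrated and powered", {
  set.seed(105)
  # type-I: same distribution, fraction significant ~ alpha (60 sims x 5 t)
  fp <- replicate(60, {
    A <- matrix(rnorm(14 * 5), 14); B <- matrix(rnorm(14 * 5), 14)
    mean(compare_conditions(A, B)$significant)
  })
  expect_lt(mean(fp), 0.10)

  # power: 3 pooled-SD shift at n = 14 per group
  hit <- replicate(20, {
    A <- matrix(rnorm(14 * 5, 3), 14); B <- matrix(rnorm(14 * 5), 14)
    mean(compare_conditions(A, B)$significant)
  })
  expect_gte(mean(hit), 0.95)

  # identical constant groups: degenerate p = 1
  C <- matrix(1, 5, 4)
  expect_true(all(compare_conditions(C, C)$p == 1))
  expect_error(compare_conditions(matrix(1, 2, 3), matrix(1, 5, 3)),
               "at least 3")
})

test_that("lag analysis recovers sign inversion and shifts", {
  set.seed(106)
  x <- rnorm(41)
  la <- erd_lrtc_lag(x, -x, max_lag = 10)
  expect_equal(la$r, -1)
  expect_equal(la$best_lag, 0)
  expect_equal(la$best_value, -1, tolerance = 1e-9)

  y <- c(rep(0, 5), x)[1:41]   # x shifted by +5 steps
  la2 <- erd_lrtc_lag(x, y, max_lag = 10)
  expect_equal(la2$best_lag, 5)

  expect_null(erd_lrtc_lag(rep(1, 41), x, max_lag = 5))

  E <- rbind(x, x, rep(2, 41))
  L <- rbind(-x, -x, rnorm(41))
  res <- erd_lrtc_lag_analysis(E, L, max_lag = 5)
  expect_equal(res$n_excluded, 1L)
  expect_equal(unname(res$best_lag[1:2]), c(0, 0))
  expect_equal(unname(which.max(res$histogram)), 6L)   # lag 0 bin
})
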