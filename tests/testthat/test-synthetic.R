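# Ground-truth generators: fGn, ARFIMA processes, and the synthetic
# movement experiment.

test_that("fGn with H = 0.5 is white noise; autocovariance matches theory", {
  x <- generate_fgn(0.5, 10000, seed = 71)
  expect_lt(abs(cor(x[-1], x[-length(x)])), 0.02)
  expect_equal(var(x), 1, tolerance = 0.05)

  # exact-method check: empirical acov at small lags matches the fGn form
  y <- generate_fgn(0.8, 20000, seed = 72)
  emp <- acf(y, lag.max = 3, plot = FALSE, demean = TRUE)$acf[2:4]
  expect_equal(as.numeric(emp), fgn_acov(1:3, 0.8), tolerance = 0.08)

  expect_error(generate_fgn(1.2, 100), "inside")
  expect_error(generate_fgn(0.7, 0), "positive")
})

test_that("DFA on exact fGn recovers H = 0.8 at window length 256", {
  hs <- vapply(1:200, function(i)
    estimate_hurst(generate_fgn(0.8, 256, seed = case_seed(73, i)))$H,
    numeric(1))
  expect_lt(abs(mean(hs) - 0.8), 0.05)
})

test_that("ARFIMA simulator: degenerate and AR(1) cases", {
  x <- simulate_arfima(n_samples = 10000, seed = 74)   # ARFIMA(0,0,0)
  expect_equal(var(x), 1, tolerance = 0.05)

  y <- simulate_arfima(0.9, 0, n_samples = 10000, seed = 75)
  expect_equal(cor(y[-1], y[-length(y)]), 0.9, tolerance = 0.02)

  expect_error(simulate_arfima(1.01, 0, n_samples = 100), "stationary")
  expect_error(simulate_arfima(d = 0.6, n_samples = 100), "0.5")
})

test_that("ARFIMA(0, 0.3, 0) has Hurst exponent near 0.8 (d = H - 0.5)", {
  hs <- vapply(1:100, function(i)
    estimate_hurst(simulate_arfima(d = 0.3, n_samples = 10^4,
                                   seed = case_seed(76, i)),
                   taper = FALSE)$H, numeric(1))
  expect_lt(abs(mean(hs) - 0.8), 0.05)
})

test_that("synthetic dataset is deterministic and correctly structured", {
  cfg <- synthetic_config(n_trials_per_condition = 2, seed = 77)
  ds1 <- synthesize_movement_dataset(cfg)
  ds2 <- synthesize_movement_dataset(cfg)
  expect_identical(ds1[[1]]$recording$signal, ds2[[1]]$recording$signal)
  expect_identical(ds1[[1]]$ground_truth, ds2[[1]]$ground_truth)

  rec <- ds1[[1]]$recording
  expect_equal(rec$channels, c("C3", "Cz", "C4"))
  expect_equal(rec$fs, 128)
  expect_equal(nrow(rec$events), 6L)
  expect_equal(sort(unique(rec$events$condition)),
               c("left", "rest", "right"))

  gt <- ds1[[1]]$ground_truth
  rest <- which(gt$condition == "rest")
  expect_true(all(gt$d[rest, ] == cfg$d_baseline))
  expect_true(all(gt$s[rest, ] == 1))
  mv <- which(gt$condition != "rest")[1]
  expect_equal(max(gt$d[mv, ]), cfg$d_peak)
  expect_equal(min(gt$s[mv, ]), 1 - cfg$alpha_suppression)

  expect_error(synthetic_config(d_baseline = 0.3, d_peak = 0.2))
  expect_error(synthetic_config(alpha_suppression = 1.2))
})

test_that("null configuration: movement and rest are exchangeable", {
  cfg <- synthetic_config(n_trials_per_condition = 8, alpha_suppression = 0,
                          d_peak = 0.12, d_baseline = 0.12, seed = 78)
  ds <- synthesize_movement_dataset(cfg)
  tr <- epoch_trials(ds[[1]]$recording)
  # compare post-onset window variance between movement and rest trials
  post <- tr$time > 0
  v_mv <- apply(tr$data[tr$condition == "right", 1, post], 1, var)
  v_rs <- apply(tr$data[tr$condition == "rest", 1, post], 1, var)
  expect_gt(wilcox.test(v_mv, v_rs)$p.value, 0.05)
})

test_that("rest-trial alpha power is stationary across windows", {
  cfg <- synthetic_config(n_trials_per_condition = 6, seed = 79)
  ds <- synthesize_movement_dataset(cfg)
  tr <- epoch_trials(ds[[1]]$recording)
  rest <- which(tr$condition == "rest")
  slopes <- vapply(rest, function(i) {
    ws <- sliding_windows(tr$data[i, 1, ], tr$fs, t_start = -3)
    bp <- apply(ws$data, 1, alpha_band_power, fs = tr$fs)
    unname(coef(lm(bp ~ ws$t))[2] / mean(bp))   # relative trend per second
  }, numeric(1))
  expect_gt(t.test(slopes)$p.value, 0.05)
})

test_that("windowed DFA tracks the programmed d(t) ramp (trial-averaged)", {
  cfg <- synthetic_config(n_trials_per_condition = 20, seed = 80)
  ds <- synthesize_movement_dataset(cfg)
  tr <- epoch_trials(ds[[1]]$recording)
  gt <- ds[[1]]$ground_truth
  mv <- which(tr$condition != "rest")   # 40 movement trials
  Hm <- sapply(mv, function(i) {
    ws <- sliding_windows(tr$data[i, 1, ], tr$fs, t_start = -3)
    apply(ws$data, 1, function(w) estimate_hurst(w)$H)
  })
  ws_t <- sliding_windows(tr$data[1, 1, ], tr$fs, t_start = -3)$t
  target <- sapply(ws_t, function(tt)
    mean(gt$d[mv[1], gt$time > tt - 2 & gt$time <= tt])) + 0.5
  expect_lt(mean(abs(rowMeans(Hm) - target)), 0.1)
})
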