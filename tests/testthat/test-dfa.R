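# DFA: box sizes, fluctuation function, Hurst estimation, ML-DFA
# validation, smoothing, and ACF/spectrum characterization.

test_that("select_box_sizes spans [n_min, N/4] on a log2 grid", {
  s <- select_box_sizes(256)
  expect_equal(s[1], 10L)
  expect_equal(s[length(s)], 64L)
  expect_true(all(diff(s) > 0))
  expect_lte(length(s), 25L)
  # roughly equidistant on log2 scale before rounding
  expect_lt(max(abs(diff(log2(s)) - mean(diff(log2(s))))), 0.15)

  expect_equal(select_box_sizes(40), 10L)
  expect_error(select_box_sizes(39), "too short")
})

test_that("dfa_fluctuations matches the naive loop oracle to 1e-10", {
  set.seed(11)
  for (i in 1:50) {
    N <- sample(32:64, 1)
    x <- rnorm(N)
    ns <- c(8L, 16L)
    expect_equal(dfa_fluctuations(x, ns), naive_dfa_fluctuations(x, ns),
                 tolerance = 1e-10)
  }
})

test_that("constant series is flagged degenerate", {
  expect_lt(max(dfa_fluctuations(rep(3.7, 256), c(10L, 32L))), 1e-8)
  r <- estimate_hurst(rep(1, 256), taper = FALSE)
  expect_true(is.na(r$H))
  expect_false(r$valid)
})

test_that("DFA slope recovers known exponents (white noise, random walk)", {
  # white noise: slope 0.5; mean over 100 seeds (sd of mean ~ 0.01)
  hs <- vapply(1:100, function(i) {
    set.seed(case_seed(21, i))
    estimate_hurst(rnorm(256), taper = FALSE)$H
  }, numeric(1))
  expect_lt(abs(mean(hs) - 0.5), 0.05)

  # integrated white noise (Brownian path): slope 1.5
  hb <- vapply(1:50, function(i) {
    set.seed(case_seed(22, i))
    estimate_hurst(cumsum(rnorm(2048)), taper = FALSE)$H
  }, numeric(1))
  expect_lt(abs(mean(hb) - 1.5), 0.1)
  # white noise H ~ 0.5 means LRTC is not declared (criterion: 0.5 < H < 1)
  expect_false(estimate_hurst(rnorm(256), taper = FALSE)$lrtc)
})

test_that("F(n) is nondecreasing in n for integrated noise inputs", {
  frac_violations <- vapply(1:20, function(i) {
    set.seed(case_seed(23, i))
    Fn <- dfa_fluctuations(cumsum(rnorm(512)), select_box_sizes(512))
    expect_gt(Fn[length(Fn)], Fn[1])
    mean(diff(Fn) < 0)
  }, numeric(1))
  # adjacent deduplicated sizes differ by as little as 10%, so rare small
  # inversions from realization noise are expected
  expect_lt(mean(frac_violations), 0.1)
})

test_that("estimate_hurst on exact fGn is close to target (spot check)", {
  hs <- vapply(1:100, function(i)
    estimate_hurst(generate_fgn(0.7, 256, seed = case_seed(24, i)))$H,
    numeric(1))
  expect_lt(abs(mean(hs) - 0.7), 0.05)
})

test_that("ML-DFA selects linear for exact power laws, rejects crossovers", {
  r <- estimate_hurst(generate_fgn(0.6, 256, seed = 1))
  r$fluctuations <- 0.3 * r$box_sizes^0.8
  r <- validate_mldfa(r)
  expect_identical(r$mldfa_best_model, "linear")
  expect_true(r$valid)

  # sharp crossover 0.5 -> 1.0 at n = 25: a bent model must win
  r2 <- r
  r2$fluctuations <- ifelse(r2$box_sizes <= 25, r2$box_sizes^0.5,
                            25^0.5 * (r2$box_sizes / 25)^1.0)
  r2 <- validate_mldfa(r2)
  expect_false(identical(r2$mldfa_best_model, "linear"))
  expect_false(r2$valid)

  r3 <- r
  r3$box_sizes <- r3$box_sizes[1:5]
  r3$fluctuations <- r3$fluctuations[1:5]
  expect_error(validate_mldfa(r3), "at least 6")
})

test_that("exponential smoothing follows the closed-form response", {
  expect_equal(smooth_hurst_series(c(0.6, 0.7, 0.8), 1), c(0.6, 0.7, 0.8))
  expect_equal(smooth_hurst_series(rep(0.63, 10), 0.3), rep(0.63, 10))

  step <- c(rep(0, 5), rep(1, 10))
  sm <- smooth_hurst_series(step, 0.5)
  # three samples after the step the smoother reaches 1 - (1-lambda)^3
  expect_equal(sm[8], 1 - 0.5^3)

  # missing values carried forward
  sm2 <- smooth_hurst_series(c(0.5, NA, 0.7), 0.5)
  expect_equal(sm2[2], 0.5)
  expect_equal(sm2[3], 0.5 * 0.7 + 0.5 * 0.5)

  expect_error(smooth_hurst_series(c(1, 2), 0), "smoothing_factor")
  expect_error(smooth_hurst_series(c(1, 2), 1.5), "smoothing_factor")
})

test_that("ACF/spectrum characterization identifies LRTC vs SRD", {
  set.seed(31)
  wn <- rnorm(4096)
  ch <- characterize_acf_spectrum(wn, fs = 128, max_lag = 20)
  expect_equal(ch$acf[1], 1)
  expect_lt(max(abs(ch$acf[-1])), 0.1)
  expect_lt(abs(ch$beta), 0.25)
  expect_false(ch$lrtc_slope)

  ar1 <- simulate_arfima(0.9, 0, n_samples = 8192, seed = 32)
  ch2 <- characterize_acf_spectrum(ar1, fs = 128, max_lag = 5)
  expect_equal(ch2$acf[2:4], 0.9^(1:3), tolerance = 0.1)

  expect_error(characterize_acf_spectrum(rep(1, 100), fs = 128, max_lag = 10),
               "zero-variance")
  expect_error(characterize_acf_spectrum(rnorm(64), fs = 128, max_lag = 64),
               "max_lag")
})

test_that("relation chain: beta ~ 2d and H ~ (1+beta)/2 on ARFIMA(0,d,0)", {
  # spectral slope fitted per realization, then averaged
  betas <- hs <- numeric(40)
  for (i in 1:40) {
    x <- simulate_arfima(d = 0.3, n_samples = 2048,
                         seed = case_seed(33, i))
    ch <- characterize_acf_spectrum(x, fs = 128, max_lag = 10)
    betas[i] <- ch$beta
    hs[i] <- estimate_hurst(x, taper = FALSE)$H
  }
  expect_lt(abs(mean(betas) - 0.6), 0.1)
  expect_true(mean(betas) >= 0.5 && mean(betas) <= 1.5)  # inside LRTC range
  expect_lt(abs(mean((1 + betas) / 2) - mean(hs)), 0.1)
})
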