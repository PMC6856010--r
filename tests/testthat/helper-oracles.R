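# Independent brute-force oracles, deliberately written with different
# machinery (lm(), gamma-function coefficients, explicit loops) than the
# package implementations they check.

# naive DFA: profile, explicit per-box lm() detrending; the leftover
# samples (N not divisible by n) are covered by repeating the boxes from
# the opposite end of the same profile (Kantelhardt 2N_s-segment variant)
naive_dfa_fluctuations <- function(x, box_sizes) {
  Y <- cumsum(x - mean(x))
  N <- length(Y)
  box_ss <- function(seg) {
    tt <- seq_along(seg)
    sum(residuals(lm(seg ~ tt))^2)
  }
  sapply(box_sizes, function(n) {
    nb <- floor(N / n)
    ss <- 0
    for (b in seq_len(nb)) {
      ss <- ss + box_ss(Y[((b - 1) * n + 1):(b * n)])
      ss <- ss + box_ss(Y[(N - b * n + 1):(N - (b - 1) * n)])
    }
    sqrt(ss / (2 * nb * n))
  })
}

# naive fractional differencing via Gamma-function binomial coefficients
# and an explicit O(N^2) convolution
naive_fracdiff <- function(x, d) {
  n <- length(x)
  k <- 0:(n - 1)
  b <- gamma(k - d) / (gamma(k + 1) * gamma(-d))
  b[1] <- 1
  y <- numeric(n)
  for (t in seq_len(n)) y[t] <- sum(b[1:t] * x[t:1])
  y
}

# theoretical fGn autocovariance
fgn_acov <- function(k, H) {
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

# deterministic per-case seed from a base seed and case index
case_seed <- function(base, i) (base * 1000L + i * 7L) %% .Machine$integer.max

sine_wave <- function(freq, fs, dur_s, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (seq_len(round(dur_s * fs)) - 1) / fs + phase)
}
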