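#' Exact fractional Gaussian noise by circulant embedding
#'
#' Davies-Harte / Wood-Chan simulation: the target autocovariance
#' \eqn{\gamma(k) = (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})/2} is embedded in a
#' circulant matrix whose eigenvalues are obtained by FFT, giving a
#' realization with *exactly* the fGn covariance (no spectral
#' approximation).  Mean 0, unit variance.  Serves as ground truth for
#' validating Hurst estimators on short windows.
#'
#' @param H Hurst exponent, in (0, 1).
#' @param n_samples series length (>= 1).
#' @param seed optional integer seed.
#' @return numeric vector of length `n_samples`.
#' @export
#' @examples
#' x <- generate_fgn(0.7, 256, seed = 1)
generate_fgn <- function(H, n_samples, seed = NULL) {
  stopifnot(is_scalar_number(H))
  if (H <= 0 || H >= 1) stop("H must lie strictly inside (0, 1)")
  if (!is_scalar_number(n_samples) || n_samples < 1)
    stop("n_samples must be a positive integer")
  n <- as.integer(n_samples)
  if (n == 1L) return(with_seed(seed, stats::rnorm(1)))

  k <- 0:(n - 1L)
  gam <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  m <- 2L * (n - 1L)
  row <- c(gam, gam[(n - 1L):2L])
  lam <- Re(stats::fft(row))
  # nonnegative in theory for fGn; clamp tiny numerical negatives
  if (min(lam) < -1e-8 * max(lam)) stop("circulant embedding failed")
  lam[lam < 0] <- 0

  half <- m %/% 2L
  z <- complex(length.out = m)
  idx <- 2L:half
  with_seed(seed, {
    z[1L] <- sqrt(lam[1L] / m) * stats::rnorm(1)
    z[half + 1L] <- sqrt(lam[half + 1L] / m) * stats::rnorm(1)
    re <- stats::rnorm(half - 1L)
    im <- stats::rnorm(half - 1L)
    z[idx] <- sqrt(lam[idx] / (2 * m)) * complex(real = re, imaginary = im)
  })
  z[m + 2L - idx] <- Conj(z[idx])
  Re(stats::fft(z))[seq_len(n)]
}

#' Simulate an ARFIMA(p, d, q) process
#'
#' Draws Gaussian innovations, applies the ARMA(p, q) recursion
#' \eqn{(1-\sum \phi_i B^i) W_t = (1+\sum \theta_i B^i) \epsilon_t}, then
#' fractionally integrates by `d` (the inverse of the binomial
#' fractional-differencing operator).  A burn-in prefix is simulated and
#' discarded to remove initialization transients.
#'
#' @param ar_coeffs AR coefficients \eqn{\phi_1..\phi_p} (may be empty).
#' @param d fractional integration parameter, `|d| < 0.5`.
#' @param ma_coeffs MA coefficients \eqn{\theta_1..\theta_q} (may be empty).
#' @param n_samples output length.
#' @param innovation_sd standard deviation of the innovations.
#' @param seed optional integer seed.
#' @param burn_in samples simulated before and dropped from the output.
#' @return numeric vector of length `n_samples`.
#' @export
#' @examples
#' x <- simulate_arfima(ar_coeffs = 0.5, d = 0.25, n_samples = 512, seed = 1)
simulate_arfima <- function(ar_coeffs = numeric(), d = 0,
                            ma_coeffs = numeric(), n_samples,
                            innovation_sd = 1, seed = NULL,
                            burn_in = 1024L) {
  stopifnot(is.numeric(ar_coeffs), is.numeric(ma_coeffs),
            is_scalar_number(d), is_scalar_number(n_samples),
            n_samples >= 1, innovation_sd > 0, burn_in >= 0)
  if (abs(d) >= 0.5) stop("|d| must be < 0.5 for a stationary ARFIMA process")
  p <- length(ar_coeffs)
  if (p > 0) {
    roots <- polyroot(c(1, -ar_coeffs))
    if (any(Mod(roots) <= 1 + 1e-8))
      stop("AR polynomial has roots on or inside the unit circle: ",
           "the process is not stationary")
  }
  n_tot <- as.integer(n_samples) + as.integer(burn_in)
  eps <- with_seed(seed, stats::rnorm(n_tot, sd = innovation_sd))

  w <- eps
  q <- length(ma_coeffs)
  if (q > 0) {
    w <- fft_convolve_head(eps, c(1, ma_coeffs))
  }
  if (p > 0) {
    w <- as.numeric(stats::filter(w, ar_coeffs, method = "recursive"))
  }
  x <- if (d != 0) fractional_integrate(w, d) else w
  x[(n_tot - as.integer(n_samples) + 1L):n_tot]
}
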