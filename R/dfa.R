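#' Box sizes for detrended fluctuation analysis
#'
#' Returns `count` box sizes equidistant on the log2 scale between `n_min`
#' and `N/4`, rounded to integers and deduplicated.  The `[10, N/4]` range
#' keeps every scale within the admissible band for linearly detrended DFA
#' of a signal band-passed between 0.5 and 45 Hz.
#'
#' @param N series length in samples.
#' @param n_min smallest box size (default 10).
#' @param count number of box sizes before deduplication (default 25).
#' @return increasing integer vector of box sizes.
#' @export
#' @examples
#' select_box_sizes(256)
select_box_sizes <- function(N, n_min = 10L, count = 25L) {
  stopifnot(is_scalar_number(N), is_scalar_number(n_min),
            is_scalar_number(count), n_min >= 4, count >= 1)
  if (N < 4 * n_min)
    stop("series too short for DFA: need N >= ", 4 * n_min,
         " to place box sizes in [", n_min, ", N/4]")
  sizes <- 2^seq(log2(n_min), log2(N / 4), length.out = count)
  unique(as.integer(round(sizes)))
}

#' DFA root-mean-square fluctuations
#'
#' The series is mean-subtracted and integrated to a profile
#' \eqn{Y_k = \sum_{i \le k} (X_i - \bar X)}; for each box size `n` the
#' profile is split into `floor(N/n)` non-overlapping boxes, a least-squares
#' line is removed per box, and the RMS residual is computed.  Because `N`
#' is generally not divisible by `n`, boxes are taken from both the forward
#' and the time-reversed direction and the two mean-square fluctuations
#' averaged (Kantelhardt variant).
#'
#' @param series numeric series.
#' @param box_sizes integer box sizes, each `<= length(series)`.
#' @return numeric vector `F(n)`, one entry per box size.
#' @export
dfa_fluctuations <- function(series, box_sizes) {
  x <- as.numeric(series)
  N <- length(x)
  stopifnot(N >= 4, all(is.finite(x)), all(box_sizes >= 2),
            max(box_sizes) <= N)
  Y <- cumsum(x - mean(x))
  vapply(as.integer(box_sizes), function(n) {
    nb <- N %/% n
    # forward boxes and backward (time-reversed) boxes in one matrix
    seg <- c(Y[seq_len(nb * n)], Y[(N - nb * n + 1L):N])
    sqrt(.dfa_box_ss(seg, n, 2L * nb) / (2 * nb * n))
  }, numeric(1))
}

# total sum of squared residuals of per-box linear detrending; the profile
# segment has length nb*n and is reshaped into an n x nb matrix
.dfa_box_ss <- function(Yseg, n, nb) {
  M <- matrix(Yseg, nrow = n, ncol = nb)
  t1 <- as.numeric(seq_len(n))
  Sx <- sum(t1); Sxx <- sum(t1 * t1)
  den <- n * Sxx - Sx * Sx
  Sy <- colSums(M)
  Sxy <- as.numeric(crossprod(t1, M))
  if (den == 0) {            # n == 1 cannot happen (box_sizes >= 2)
    slope <- 0; inter <- Sy / n
  } else {
    slope <- (n * Sxy - Sx * Sy) / den
    inter <- (Sy - slope * Sx) / n
  }
  Syy <- colSums(M * M)
  ss <- Syy - 2 * inter * Sy - 2 * slope * Sxy + n * inter^2 +
    2 * inter * slope * Sx + slope^2 * Sxx
  sum(pmax(ss, 0))
}

#' Estimate the Hurst exponent of a short window by DFA
#'
#' Applies an optional Hanning taper to the raw window (to limit edge
#' effects on 2 s segments), computes [dfa_fluctuations()] over
#' [select_box_sizes()] scales, and takes the slope of the least-squares
#' line through `(log2 n, log2 F(n))` as the Hurst exponent estimate.
#' Long-range temporal correlation is declared present when
#' `0.5 < H < 1`.
#'
#' @param window numeric series (>= 40 samples) or an `analysis_window`.
#' @param taper apply a Hanning taper before integrating (default TRUE).
#' @param n_min,count passed to [select_box_sizes()].
#' @return object of class `dfa_result`: list with `H`, `box_sizes`,
#'   `fluctuations`, `fit_r2`, `lrtc` (logical, `0.5 < H < 1`),
#'   `mldfa_best_model` (filled by [validate_mldfa()]), `valid`.
#' @export
#' @examples
#' r <- estimate_hurst(generate_fgn(0.7, 256, seed = 1))
#' r$H
estimate_hurst <- function(window, taper = TRUE, n_min = 10L, count = 25L) {
  x <- if (inherits(window, "analysis_window")) window$samples else
    as.numeric(window)
  N <- length(x)
  if (N < 4 * n_min)
    stop("window too short for DFA (need >= ", 4 * n_min, " samples)")
  degenerate <- stats::var(x) == 0       # judged on the raw window
  if (isTRUE(taper)) x <- x * hann_window(N)
  sizes <- select_box_sizes(N, n_min = n_min, count = count)
  Fn <- dfa_fluctuations(x, sizes)
  res <- structure(list(H = NA_real_, box_sizes = sizes, fluctuations = Fn,
                        fit_r2 = NA_real_, lrtc = NA,
                        mldfa_best_model = NA_character_, valid = FALSE),
                   class = "dfa_result")
  if (degenerate || any(Fn <= 0)) {
    # e.g. constant input: H undefined
    return(res)
  }
  lx <- log2(sizes); ly <- log2(Fn)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  res$H <- unname(fit$coefficients[2L])
  res$fit_r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)
  res$lrtc <- res$H > 0.5 && res$H < 1
  res$valid <- res$H > 0   # provisional until ML-DFA is run
  res
}

#' @export
print.dfa_result <- function(x, ...) {
  cat("DFA result: H =", format(x$H, digits = 4),
      "| scales", min(x$box_sizes), "-", max(x$box_sizes),
      "| valid:", x$valid,
      if (!is.na(x$mldfa_best_model)) paste("| ML-DFA:", x$mldfa_best_model),
      "\n")
  invisible(x)
}

#' Validate DFA scaling by maximum-likelihood model comparison (ML-DFA)
#'
#' A single Hurst exponent is meaningful only if the log-log DFA plot is
#' linear.  Candidate models -- linear, polynomials of order 2-5,
#' logarithmic `a*log(x)+b`, and exponential `a*exp(b*x)+c` -- are fitted
#' to `(log2 n, log2 F(n))` by Gaussian maximum likelihood and compared
#' with a small-sample information criterion (AICc).  Because fluctuation
#' values at neighbouring scales are computed from the same samples, their
#' residuals are strongly correlated and raw AICc differences overstate the
#' evidence; the winner is therefore chosen by a parsimony rule: among all
#' models within 2 AICc units of the minimum, the one with the fewest
#' parameters wins, with ties broken in favour of the linear model.  The
#' estimate is valid iff the linear model wins and `H > 0`.
#'
#' @param result a `dfa_result` with at least 6 retained box sizes.
#' @return the updated `dfa_result` with `mldfa_best_model` and `valid` set.
#' @export
validate_mldfa <- function(result) {
  stopifnot(inherits(result, "dfa_result"))
  if (length(result$box_sizes) < 6L)
    stop("ML-DFA needs at least 6 (box size, fluctuation) pairs")
  if (any(result$fluctuations <= 0)) {
    result$mldfa_best_model <- "degenerate"
    result$valid <- FALSE
    return(result)
  }
  x <- log2(result$box_sizes)
  y <- log2(result$fluctuations)
  m <- length(x)

  rss_of <- function(fitted) max(sum((y - fitted)^2), 1e-10)
  aicc <- function(rss, k) {
    # k model coefficients + 1 variance parameter
    K <- k + 1
    m * log(rss / m) + 2 * K + if (m - K - 1 > 0) 2 * K * (K + 1) / (m - K - 1) else Inf
  }

  cand <- list()
  npar <- c(linear = 2, polynomial_2 = 3, polynomial_3 = 4,
            polynomial_4 = 5, polynomial_5 = 6, logarithmic = 2,
            exponential = 3)
  for (deg in 1:5) {
    X <- outer(x, 0:deg, `^`)
    fit <- try(stats::lm.fit(X, y), silent = TRUE)
    if (inherits(fit, "try-error")) next
    nm <- if (deg == 1L) "linear" else paste0("polynomial_", deg)
    cand[[nm]] <- aicc(rss_of(y - fit$residuals), deg + 1L)
  }
  logfit <- try(stats::lm.fit(cbind(1, log(x)), y), silent = TRUE)
  if (!inherits(logfit, "try-error"))
    cand[["logarithmic"]] <- aicc(rss_of(y - logfit$residuals), 2L)
  expfit <- .fit_exponential(x, y)
  if (!is.null(expfit))
    cand[["exponential"]] <- aicc(rss_of(expfit), 3L)

  scores <- unlist(cand)
  # parsimony rule: fewest parameters among the supported set (delta <= 2),
  # tie to linear
  supported <- names(scores)[scores <= min(scores) + 2]
  supported <- supported[npar[supported] == min(npar[supported])]
  best <- if ("linear" %in% supported) "linear" else
    supported[which.min(scores[supported])]
  result$mldfa_best_model <- best
  result$valid <- identical(best, "linear") && is.finite(result$H) &&
    result$H > 0
  result
}

# a*exp(b*x) + c fitted by Nelder-Mead on the profile over b; returns
# fitted values or NULL on failure
.fit_exponential <- function(x, y) {
  prof_rss <- function(b) {
    e <- exp(pmin(b * x, 50))
    X <- cbind(1, e)
    fit <- try(stats::lm.fit(X, y), silent = TRUE)
    if (inherits(fit, "try-error") || any(!is.finite(fit$coefficients)))
      return(list(rss = Inf))
    list(rss = sum(fit$residuals^2), fitted = y - fit$residuals)
  }
  best <- NULL; best_rss <- Inf
  for (b0 in c(-1, -0.3, -0.1, 0.1, 0.3, 1)) {
    op <- try(suppressWarnings(
      stats::optimize(function(b) prof_rss(b)$rss,
                      interval = c(b0 - 0.5, b0 + 0.5))), silent = TRUE)
    if (inherits(op, "try-error")) next
    if (op$objective < best_rss) {
      best_rss <- op$objective
      best <- prof_rss(op$minimum)$fitted
    }
  }
  best
}

#' Exponentially smooth a Hurst time course
#'
#' First-order exponential smoother
#' \eqn{s_t = \lambda H_t + (1-\lambda) s_{t-1}}, \eqn{s_1 = H_1}, used to
#' stabilize per-window Hurst estimates over consecutive sliding windows.
#' Missing values are carried forward (the previous smoothed value is
#' emitted and the state is unchanged).
#'
#' @param H_t numeric series, possibly with `NA`s.
#' @param smoothing_factor \eqn{\lambda} in (0, 1]; 1 = no smoothing.
#' @return smoothed series, same length.
#' @export
smooth_hurst_series <- function(H_t, smoothing_factor = 0.3) {
  lam <- smoothing_factor
  if (!is_scalar_number(lam) || lam <= 0 || lam > 1)
    stop("smoothing_factor must lie in (0, 1]")
  n <- length(H_t)
  if (n == 0L) stop("empty Hurst series")
  out <- numeric(n)
  s <- NA_real_
  for (i in seq_len(n)) {
    h <- H_t[i]
    if (is.na(h)) {
      out[i] <- s
    } else {
      s <- if (is.na(s)) h else lam * h + (1 - lam) * s
      out[i] <- s
    }
  }
  out
}

#' Autocorrelation and spectral characterization of a window
#'
#' Descriptive identification of long- vs short-range dependence: the
#' sample ACF and PACF, and the slope of the log-log periodogram.  A
#' power-law ACF \eqn{\rho(t) = C t^{-\alpha}} and a linear log-log
#' spectrum \eqn{S(f) = B f^{-\beta}} with \eqn{\beta} between 0.5 and 1.5
#' indicate long-range temporal correlation; for noise-like signals
#' \eqn{\beta = 2d} and `H_from_beta` reports \eqn{H = (1+\beta)/2}.
#'
#' @param window numeric series or `analysis_window`.
#' @param fs sampling rate in Hz (taken from the window if available).
#' @param max_lag maximum ACF/PACF lag in samples.
#' @param freq_range frequency band (Hz) over which the spectral slope is
#'   fitted; default `c(0.5, 45)`, the broadband analysis band.
#' @return object of class `spectral_characterization`: `acf`, `pacf`,
#'   `beta` (spectral exponent \eqn{\hat\beta}), `B` (spectral constant),
#'   `alpha_acf`, `C_acf` (ACF power-law fit, `NA` if no positive ACF run),
#'   `lrtc_slope` (`TRUE` iff \eqn{|\hat\beta| \in [0.5, 1.5]}),
#'   `H_from_beta`.
#' @export
characterize_acf_spectrum <- function(window, fs = NULL, max_lag = 50L,
                                      freq_range = c(0.5, 45)) {
  x <- if (inherits(window, "analysis_window")) {
    fs <- fs %||% window$fs
    window$samples
  } else as.numeric(window)
  N <- length(x)
  if (max_lag >= N) stop("max_lag must be smaller than the window length")
  if (stats::var(x) == 0) stop("zero-variance window")
  fs <- fs %||% 128

  acf_v <- as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                                 demean = TRUE)$acf)
  pacf_v <- as.numeric(stats::pacf(x, lag.max = max_lag, plot = FALSE)$acf)

  xc <- x - mean(x)
  P <- Mod(stats::fft(xc))^2 / N
  f <- (seq_len(N) - 1L) * fs / N
  keep <- f >= max(freq_range[1], fs / N) & f <= min(freq_range[2], fs / 2) &
    P > 0
  fit <- stats::lm.fit(cbind(1, log(f[keep])), log(P[keep]))
  beta <- -unname(fit$coefficients[2L])
  B <- exp(unname(fit$coefficients[1L]))

  # ACF power-law fit over the initial run of positive autocorrelations
  alpha_acf <- NA_real_; C_acf <- NA_real_
  pos <- which(acf_v[-1L] > 0)
  run <- if (length(pos) && pos[1L] == 1L) seq_len(which.min(c(diff(pos) == 1, FALSE))) else integer()
  if (length(run) >= 3L) {
    lg <- run
    afit <- stats::lm.fit(cbind(1, log(lg)), log(acf_v[lg + 1L]))
    alpha_acf <- -unname(afit$coefficients[2L])
    C_acf <- exp(unname(afit$coefficients[1L]))
  }

  structure(list(acf = acf_v, pacf = pacf_v, beta = beta, B = B,
                 alpha_acf = alpha_acf, C_acf = C_acf,
                 lrtc_slope = abs(beta) >= 0.5 && abs(beta) <= 1.5,
                 H_from_beta = (1 + beta) / 2),
            class = "spectral_characterization")
}
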