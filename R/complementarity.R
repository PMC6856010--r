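# Ablation experiments probing the complementarity of broadband LRTC and
# narrowband ERD: remove one process and check the other is unchanged.

#' Suppress ERD by fixing the alpha magnitude spectrum within a trial
#'
#' One donor window is drawn uniformly at random per trial; in every
#' window of that trial the discrete-Fourier *magnitudes* of the bins
#' whose centre frequency lies inside `band` (inclusive; 11 bins for 2 s
#' windows at 128 Hz) are replaced by the donor's magnitudes while each
#' window's own phases are kept.  Conjugate symmetry is enforced so the
#' inverse transform is real, and all out-of-band bins are untouched.
#' Band power is thereby constant across the trial, flattening the ERD
#' trace while leaving broadband structure intact.
#'
#' @param windows a `window_set` (from [sliding_windows()]) or a plain
#'   windows x samples matrix.
#' @param fs sampling rate in Hz (taken from the `window_set` if given).
#' @param band frequency band whose magnitudes are fixed (Hz, inclusive).
#' @param seed optional seed for the donor draw.
#' @return object like the input, with modified samples and attribute
#'   `donor` (the donor window index).
#' @export
suppress_erd <- function(windows, fs = NULL, band = c(8, 13), seed = NULL) {
  ws <- NULL
  if (inherits(windows, "window_set")) {
    ws <- windows
    fs <- fs %||% ws$fs
    M <- ws$data
  } else M <- as.matrix(windows)
  if (is.null(fs)) stop("fs required")
  if (nrow(M) < 2L) stop("need at least 2 windows per trial")
  N <- ncol(M)
  donor <- with_seed(seed, sample.int(nrow(M), 1L))

  freq <- (seq_len(N) - 1L) * fs / N
  pos <- which(freq >= band[1] & freq <= band[2] & freq <= fs / 2)
  Xd <- stats::fft(M[donor, ])
  mag_d <- Mod(Xd[pos])

  out <- M
  for (i in seq_len(nrow(M))) {
    X <- stats::fft(M[i, ])
    ph <- Arg(X[pos])
    X[pos] <- mag_d * exp(1i * ph)
    mirror <- N + 2L - pos
    ok <- mirror >= 1L & mirror <= N & mirror != pos
    X[mirror[ok]] <- Conj(X[pos][ok])
    out[i, ] <- Re(stats::fft(X, inverse = TRUE)) / N
  }
  if (!is.null(ws)) {
    ws$data <- out
    attr(ws, "donor") <- donor
    return(ws)
  }
  attr(out, "donor") <- donor
  out
}

#' Remove LRTC from windows by per-window fractional differencing
#'
#' Each window is fractionally differenced by its own `d = H - 0.5`
#' (DFA-estimated), which removes the long-range temporal correlation
#' while leaving short-range structure; used to probe the effect of LRTC
#' removal on ERD.
#'
#' @param windows a `window_set` or windows x samples matrix.
#' @param taper passed to [estimate_hurst()].
#' @return object like the input with differenced samples and attribute
#'   `d` (the per-window differencing parameters).
#' @export
remove_lrtc <- function(windows, taper = TRUE) {
  ws <- NULL
  if (inherits(windows, "window_set")) {
    ws <- windows
    M <- ws$data
  } else M <- as.matrix(windows)
  ds <- numeric(nrow(M))
  out <- M
  for (i in seq_len(nrow(M))) {
    H <- estimate_hurst(M[i, ], taper = taper)$H
    if (is.na(H)) {
      ds[i] <- NA_real_
      next
    }
    ds[i] <- H - 0.5
    out[i, ] <- fractional_difference(M[i, ], ds[i])
  }
  if (!is.null(ws)) {
    ws$data <- out
    attr(ws, "d") <- ds
    return(ws)
  }
  attr(out, "d") <- ds
  out
}

#' Per-time-point Mann-Whitney comparison of two groups of traces
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test at every window
#' label; the unit of observation is whatever the rows are (participants
#' for grand-average analyses, trials for within-participant analyses).
#'
#' @param traces_a,traces_b numeric matrices, observations x time, on the
#'   same time axis.
#' @param alpha significance level for the mask.
#' @return list with `p` (per-time p-values), `significant` (p < alpha),
#'   and `n_a`, `n_b`.
#' @export
compare_conditions <- function(traces_a, traces_b, alpha = 0.05) {
  A <- as.matrix(traces_a); B <- as.matrix(traces_b)
  if (ncol(A) != ncol(B)) stop("traces must share their time axis")
  if (nrow(A) < 3L || nrow(B) < 3L)
    stop("need at least 3 observations per group")
  p <- vapply(seq_len(ncol(A)), function(j) {
    a <- A[, j]; b <- B[, j]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(unique(c(a, b))) == 1L) return(1)   # all tied: degenerate
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  }, numeric(1))
  list(p = p, significant = p < alpha, n_a = nrow(A), n_b = nrow(B))
}

#' Correlation and cross-correlation lag between ERD and LRTC traces
#'
#' Both traces are demeaned; the normalized cross-correlation is computed
#' over lags in `[-max_lag, max_lag]` (in window steps, 100 ms units) and
#' the lag of maximum absolute cross-correlation reported together with
#' the lag-0 Pearson correlation.  A positive lag means the second trace
#' lags the first.
#'
#' @param erd_trace,lrtc_trace aligned numeric traces (same window labels).
#' @param max_lag maximum lag in window steps.
#' @return list with `r` (Pearson r at lag 0), `ccf` (named vector over
#'   lags), `best_lag`, `best_value`; `NULL` if either trace is constant.
#' @export
erd_lrtc_lag <- function(erd_trace, lrtc_trace, max_lag = 10L) {
  x <- as.numeric(erd_trace); y <- as.numeric(lrtc_trace)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) return(NULL)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NULL)
  x <- x - mean(x); y <- y - mean(y)
  n <- length(x)
  max_lag <- min(max_lag, n - 1L)
  lags <- -max_lag:max_lag
  den <- sqrt(sum(x^2) * sum(y^2))
  cc <- vapply(lags, function(k) {
    if (k >= 0) sum(x[seq_len(n - k)] * y[seq_len(n - k) + k]) / den
    else sum(x[seq_len(n + k) - k] * y[seq_len(n + k)]) / den
  }, numeric(1))
  names(cc) <- lags
  best <- which.max(abs(cc))
  list(r = stats::cor(x, y), ccf = cc,
       best_lag = lags[best], best_value = unname(cc[best]))
}

#' Lag analysis across many trials
#'
#' Applies [erd_lrtc_lag()] per trial and tabulates the distribution of
#' best lags (the single-trial cross-correlation histogram).
#'
#' @param erd_traces,lrtc_traces matrices, trials x time.
#' @param max_lag maximum lag in window steps.
#' @return list with `r` (per-trial lag-0 correlations), `best_lag`
#'   (per-trial), `histogram` (table over lags), `n_excluded`.
#' @export
erd_lrtc_lag_analysis <- function(erd_traces, lrtc_traces, max_lag = 10L) {
  E <- as.matrix(erd_traces); L <- as.matrix(lrtc_traces)
  stopifnot(dim(E)[1] == dim(L)[1], dim(E)[2] == dim(L)[2])
  rs <- lags <- rep(NA_real_, nrow(E))
  for (i in seq_len(nrow(E))) {
    la <- erd_lrtc_lag(E[i, ], L[i, ], max_lag = max_lag)
    if (is.null(la)) next
    rs[i] <- la$r
    lags[i] <- la$best_lag
  }
  list(r = rs, best_lag = lags,
       histogram = table(factor(lags[!is.na(lags)],
                                levels = -max_lag:max_lag)),
       n_excluded = sum(is.na(lags)))
}
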