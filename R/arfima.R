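# Two-stage ARFIMA(p, d, q) fitting: d = H - 0.5 from DFA, fractional
# differencing, then ARMA estimation on the short-range remainder.

# Dickey-Fuller tau (with constant) quantiles, Fuller (1976) / Banerjee et
# al.; rows = sample sizes, cols = probabilities
.adf_tau_probs <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
.adf_tau_n <- c(25, 50, 100, 250, 500, Inf)
.adf_tau_table <- matrix(c(
  -3.75, -3.33, -3.00, -2.62, -0.37,  0.00,  0.34,  0.72,
  -3.58, -3.22, -2.93, -2.60, -0.40, -0.03,  0.29,  0.66,
  -3.51, -3.17, -2.89, -2.58, -0.42, -0.05,  0.26,  0.63,
  -3.46, -3.14, -2.88, -2.57, -0.42, -0.06,  0.24,  0.62,
  -3.44, -3.13, -2.87, -2.57, -0.43, -0.07,  0.24,  0.61,
  -3.43, -3.12, -2.86, -2.57, -0.44, -0.07,  0.23,  0.60),
  nrow = 6L, byrow = TRUE)

#' Augmented Dickey-Fuller unit-root test
#'
#' Regression of the first difference on a constant, the lagged level and
#' `lags` lagged differences; the t-statistic of the lagged-level
#' coefficient is compared with the Dickey-Fuller tau distribution
#' (with-constant variant, table interpolation).  Rejection of the
#' unit-root null at 0.05 is taken as evidence of stationarity, the
#' prerequisite for estimating the ARMA part of an ARFIMA model.
#'
#' @param series numeric series, length >= 20.
#' @param lags number of lagged differences; `NULL` (default) selects by
#'   AIC up to `floor((N-1)^(1/3))`.
#' @return list with `statistic`, `p`, `stationary` (p < 0.05), `lags`.
#' @export
adf_stationarity_test <- function(series, lags = NULL) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < 20L) stop("ADF test needs at least 20 samples")
  if (stats::var(x) == 0) stop("constant series: ADF test undefined")
  k_max <- if (is.null(lags)) max(0L, floor((n - 1)^(1/3))) else as.integer(lags)
  k_set <- if (is.null(lags)) 0:k_max else k_max

  dx <- diff(x)
  best <- NULL; best_aic <- Inf
  for (k in k_set) {
    yi <- (k + 1L):(n - 1L)
    y <- dx[yi]
    X <- cbind(1, x[yi])
    if (k > 0)
      X <- cbind(X, sapply(seq_len(k), function(j) dx[yi - j]))
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    m <- length(y)
    aic <- m * log(rss / m) + 2 * (k + 2L)
    if (aic < best_aic) {
      best_aic <- aic
      best <- list(fit = fit, X = X, y = y, k = k, rss = rss, m = m)
    }
  }
  sigma2 <- best$rss / (best$m - ncol(best$X))
  XtXinv <- chol2inv(chol(crossprod(best$X)))
  tstat <- best$fit$coefficients[2L] / sqrt(sigma2 * XtXinv[2L, 2L])

  # bilinear interpolation in the tau table (clamped at the edges)
  tab_n <- vapply(seq_along(.adf_tau_probs), function(j)
    stats::approx(.adf_tau_n[-6L], .adf_tau_table[-6L, j], xout = min(n, 500),
                  rule = 2)$y, numeric(1))
  if (n > 500) tab_n <- .adf_tau_table[6L, ]
  p <- stats::approx(tab_n, .adf_tau_probs, xout = tstat, rule = 2)$y
  list(statistic = unname(tstat), p = unname(p),
       stationary = unname(p < 0.05), lags = best$k)
}

#' ARMA order selection by AIC
#'
#' Fits ARMA(p, q) for `p` in `1..p_max` and `q` in `0..p-1` to a
#' (fractionally differenced, stationary) series and returns the
#' AIC-minimizing order.  Candidates whose MA polynomial is non-invertible
#' are discarded; if every q > 0 candidate is non-invertible the choice
#' falls back to the pure AR model (which can represent the same process
#' at higher order).
#'
#' @param series numeric stationary series.
#' @param p_max maximum AR order (default 10).
#' @param q_max maximum MA order per p (default `p - 1`).
#' @return list with `p`, `q`, and `table` (data.frame of candidate fits).
#' @export
select_order <- function(series, p_max = 10L, q_max = NULL) {
  x <- as.numeric(series)
  stopifnot(length(x) > 3 * p_max)
  rows <- list()
  for (p in seq_len(p_max)) {
    for (q in 0:(if (is.null(q_max)) p - 1L else min(q_max, p - 1L))) {
      fit <- try(suppressWarnings(
        stats::arima(x, order = c(p, 0L, q), include.mean = FALSE,
                     method = "CSS-ML")), silent = TRUE)
      if (inherits(fit, "try-error")) next
      invertible <- TRUE
      if (q > 0) {
        theta <- fit$coef[grep("^ma", names(fit$coef))]
        invertible <- all(Mod(polyroot(c(1, theta))) > 1)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(p = p, q = q, aic = fit$aic, invertible = invertible)
    }
  }
  if (!length(rows)) stop("all candidate ARMA fits failed")
  tab <- do.call(rbind, rows)
  ok <- tab[tab$invertible, , drop = FALSE]
  best <- ok[which.min(ok$aic), ]
  list(p = best$p, q = best$q, table = tab)
}

#' Fit an AR(p) model by exact least squares
#'
#' Conditional least-squares estimation of
#' \eqn{X_t = \sum_{i=1}^p \phi_i X_{t-i} + \epsilon_t} (the series is
#' demeaned first), the sign convention that puts the AR polynomial on the
#' left-hand side.  Deterministic: identical input gives identical
#' coefficients.
#'
#' @param series numeric stationary series, length > 3p.
#' @param p AR order.
#' @return object of class `arfima_fit` with fields `d` (unset, `NA`),
#'   `p`, `q = 0`, `phi`, `theta`, `sigma2`, `aic`, and diagnostic slots.
#' @export
fit_ar <- function(series, p = 10L) {
  x <- as.numeric(series)
  n <- length(x)
  if (n <= 3 * p) stop("series too short: need length > 3p")
  if (stats::var(x) == 0) stop("constant series: AR design is singular")
  x <- x - mean(x)
  y <- x[(p + 1L):n]
  X <- sapply(seq_len(p), function(j) x[(p + 1L - j):(n - j)])
  qrX <- qr(X)
  if (qrX$rank < p) stop("singular AR design matrix")
  phi <- qr.coef(qrX, y)
  res <- y - X %*% phi
  m <- length(y)
  sigma2 <- sum(res^2) / m
  aic <- m * log(sigma2) + 2 * (p + 1L)
  structure(list(d = NA_real_, p = p, q = 0L, phi = as.numeric(phi),
                 theta = numeric(), sigma2 = sigma2, aic = aic,
                 residuals = as.numeric(res),
                 ljung_box_p = NA_real_, ks_p = NA_real_,
                 ljung_box_pass = NA, ks_pass = NA,
                 adf_stationary = NA, H = NA_real_),
            class = "arfima_fit")
}

#' @export
print.arfima_fit <- function(x, ...) {
  cat(sprintf("ARFIMA(%d, %s, %d) fit: d = %s, AIC = %.2f\n",
              x$p, format(x$d, digits = 3), x$q, format(x$d, digits = 3),
              x$aic))
  cat("phi:", paste(format(x$phi, digits = 3), collapse = " "), "\n")
  if (!is.na(x$ljung_box_p))
    cat(sprintf("Ljung-Box p = %.3f, KS p = %.3f, ADF stationary: %s\n",
                x$ljung_box_p, x$ks_p, x$adf_stationary))
  invisible(x)
}

#' Residual diagnostics for a fitted ARMA model
#'
#' Ljung-Box Q test for leftover autocorrelation (degrees of freedom
#' reduced by the number of fitted AR+MA parameters) and a one-sample
#' Kolmogorov-Smirnov test of normality against a normal with the
#' residuals' estimated mean and sd.  Model adequacy is non-rejection at
#' 0.05.
#'
#' @param fit an `arfima_fit`.
#' @param residuals residual series; defaults to the fit's own residuals.
#' @param lb_lag Ljung-Box lag count (default 20).
#' @return the updated `arfima_fit` with `ljung_box_p`, `ks_p` and pass
#'   flags set.
#' @export
residual_diagnostics <- function(fit, residuals = fit$residuals,
                                 lb_lag = 20L) {
  stopifnot(inherits(fit, "arfima_fit"))
  r <- as.numeric(residuals)
  if (length(r) <= lb_lag)
    stop("fewer residuals than Ljung-Box lags")
  fitdf <- min(fit$p + fit$q, lb_lag - 1L)
  lb <- stats::Box.test(r, lag = lb_lag, type = "Ljung-Box", fitdf = fitdf)
  ks <- suppressWarnings(stats::ks.test(r, "pnorm", mean(r), stats::sd(r)))
  fit$ljung_box_p <- unname(lb$p.value)
  fit$ks_p <- unname(ks$p.value)
  fit$ljung_box_pass <- fit$ljung_box_p >= 0.05
  fit$ks_pass <- fit$ks_p >= 0.05
  fit
}

#' Fit ARFIMA(p, d, 0) to one analysis window (two-stage scheme)
#'
#' Stage 1: the Hurst exponent of the raw window is estimated by DFA and
#' converted to the fractional differencing parameter `d = H - 0.5`
#' (negative `d`, i.e. anti-persistent windows, is allowed and simply
#' fractionally integrates).  Stage 2: the window is fractionally
#' differenced by `d`, checked for stationarity (ADF), and an AR(p) model
#' is fitted by least squares, followed by residual diagnostics.  With the
#' default `p = 10` the fit carries 11 parameters: `d` plus ten AR
#' coefficients.
#'
#' @param window numeric series or [analysis_window()].
#' @param p AR order (default 10).
#' @param q MA order; only `q = 0` is supported (non-invertible MA
#'   candidates are represented by the higher-order AR instead).
#' @param taper passed to [estimate_hurst()].
#' @param diagnostics run [residual_diagnostics()] (default TRUE).
#' @return an `arfima_fit` (with `H` and `d` set), or a degenerate fit with
#'   `d = NA` and attribute `reason` if the DFA estimate is invalid.
#' @export
fit_arfima_window <- function(window, p = 10L, q = 0L, taper = TRUE,
                              diagnostics = TRUE) {
  if (q != 0L) stop("only q = 0 is supported for per-window fits")
  x <- if (inherits(window, "analysis_window")) window$samples else
    as.numeric(window)
  dres <- estimate_hurst(x, taper = taper)
  if (is.na(dres$H)) {
    out <- structure(list(d = NA_real_, p = p, q = 0L,
                          phi = rep(NA_real_, p), theta = numeric(),
                          sigma2 = NA_real_, aic = NA_real_,
                          residuals = numeric(),
                          ljung_box_p = NA_real_, ks_p = NA_real_,
                          ljung_box_pass = NA, ks_pass = NA,
                          adf_stationary = NA, H = NA_real_),
                     class = "arfima_fit")
    attr(out, "reason") <- "degenerate DFA (H undefined)"
    return(out)
  }
  d <- dres$H - 0.5
  w <- fractional_difference(x - mean(x), d)
  adf <- tryCatch(adf_stationarity_test(w), error = function(e) NULL)
  fit <- fit_ar(w, p = p)
  fit$d <- d
  fit$H <- dres$H
  fit$adf_stationary <- if (is.null(adf)) NA else adf$stationary
  if (diagnostics) fit <- residual_diagnostics(fit)
  fit
}

#' Sample PACF with significance band
#'
#' Partial autocorrelations via Levinson-Durbin (as in [stats::pacf()])
#' with the usual \eqn{\pm 1.96/\sqrt{N}} band; an AR(p) process cuts off
#' after lag p.
#'
#' @param series numeric stationary series.
#' @param max_lag maximum lag.
#' @return list with `pacf`, `band`, `significant` (logical per lag).
#' @export
pacf_identification <- function(series, max_lag = 20L) {
  x <- as.numeric(series)
  if (stats::var(x) == 0) stop("zero-variance series")
  pv <- as.numeric(stats::pacf(x, lag.max = max_lag, plot = FALSE)$acf)
  band <- 1.96 / sqrt(length(x))
  list(pacf = pv, band = band, significant = abs(pv) > band)
}
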