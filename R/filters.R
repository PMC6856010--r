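# Butterworth IIR design and zero-phase filtering.
#
# No DSP package is assumed: filters are designed from the analog
# Butterworth prototype (poles on the unit half-circle), frequency-
# transformed, discretized by the bilinear transform with prewarping, and
# applied as cascaded biquad (second-order) sections for numerical
# robustness at extreme band-edge ratios (e.g. 0.5 Hz at 1024 Hz).

butter_prototype <- function(n) {
  m <- seq(-n + 1, n - 1, by = 2)
  -exp(1i * pi * m / (2 * n))   # poles; zeros empty; gain 1
}

lp2lp_zpk <- function(p, k, wo) {
  list(z = complex(0), p = p * wo, k = k * wo^length(p))
}

lp2bp_zpk <- function(p, k, wo, bw) {
  degree <- length(p)
  p_lp <- p * bw / 2
  p_bp <- c(p_lp + sqrt(p_lp^2 - wo^2), p_lp - sqrt(p_lp^2 - wo^2))
  list(z = rep(0 + 0i, degree), p = p_bp, k = k * bw^degree)
}

lp2bs_zpk <- function(p, k, wo, bw) {
  degree <- length(p)
  p_hp <- (bw / 2) / p
  p_bs <- c(p_hp + sqrt(p_hp^2 - wo^2), p_hp - sqrt(p_hp^2 - wo^2))
  z_bs <- c(rep(1i * wo, degree), rep(-1i * wo, degree))
  k_bs <- k * Re(1 / prod(-p))
  list(z = z_bs, p = p_bs, k = k_bs)
}

bilinear_zpk <- function(z, p, k, fs) {
  fs2 <- 2 * fs
  degree <- length(p) - length(z)
  z_d <- (fs2 + z) / (fs2 - z)
  p_d <- (fs2 + p) / (fs2 - p)
  z_d <- c(z_d, rep(-1 + 0i, degree))
  k_d <- k * Re(prod(fs2 - z) / prod(fs2 - p))
  list(z = z_d, p = p_d, k = k_d)
}

# pair conjugate roots; returns list of complex pairs (real roots paired
# together in order)
.conj_pairs <- function(r) {
  used <- logical(length(r))
  pairs <- list()
  idx_real <- which(abs(Im(r)) < 1e-9)
  idx_cplx <- which(abs(Im(r)) >= 1e-9)
  for (i in idx_cplx) {
    if (used[i]) next
    j <- setdiff(idx_cplx[!used[idx_cplx] &
                            abs(r[idx_cplx] - Conj(r[i])) < 1e-7], i)
    if (!length(j)) stop("unpaired complex root in filter design")
    j <- j[1L]
    used[c(i, j)] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(r[i], r[j])
  }
  re <- r[idx_real]
  while (length(re) >= 2) {
    pairs[[length(pairs) + 1L]] <- re[1:2]
    re <- re[-(1:2)]
  }
  if (length(re)) pairs[[length(pairs) + 1L]] <- re[1L]
  pairs
}

# convert zpk to second-order sections (matrix, rows = c(b0,b1,b2,a0,a1,a2));
# zeros are assigned greedily to the nearest pole pair
zpk2sos <- function(z, p, k) {
  pp <- .conj_pairs(p)
  # order pole pairs by closeness to the unit circle (most resonant first)
  pp <- pp[order(-vapply(pp, function(q) max(Mod(q)), numeric(1)))]
  zleft <- z
  sos <- matrix(0, nrow = length(pp), ncol = 6L)
  for (i in seq_along(pp)) {
    pol <- pp[[i]]
    ztake <- complex(0)
    for (rep_i in seq_len(min(length(pol), length(zleft)))) {
      j <- which.min(Mod(zleft - mean(pol)))
      ztake <- c(ztake, zleft[j])
      # if the chosen zero is complex, its conjugate must come too
      if (abs(Im(zleft[j])) > 1e-9) {
        jc <- which(abs(zleft - Conj(zleft[j])) < 1e-7)
        jc <- setdiff(jc, j)[1L]
        if (!is.na(jc)) {
          ztake <- c(ztake, zleft[jc])
          zleft <- zleft[-c(j, jc)]
        } else zleft <- zleft[-j]
      } else zleft <- zleft[-j]
      if (length(ztake) >= length(pol)) break
    }
    b <- poly_from_roots(ztake)
    a <- poly_from_roots(pol)
    b <- c(b, rep(0, 3 - length(b)))
    a <- c(a, rep(0, 3 - length(a)))
    sos[i, ] <- c(b, a)
  }
  sos[1L, 1:3] <- sos[1L, 1:3] * k
  sos
}

#' Design a digital Butterworth filter
#'
#' Analog prototype, band transform, bilinear discretization with
#' prewarping; returned as second-order sections for numerical stability.
#'
#' @param order filter order of the analog prototype (band-pass/stop
#'   designs double the final order).
#' @param w critical frequency in Hz (length 1 for low/high, 2 for
#'   pass/stop).
#' @param fs sampling rate in Hz.
#' @param type one of "low", "high", "pass", "stop".
#' @return a `sos_filter`: list with `sos` matrix and design metadata.
#' @export
butter_filter <- function(order, w, fs,
                          type = c("low", "high", "pass", "stop")) {
  type <- match.arg(type)
  stopifnot(order >= 1, all(w > 0), all(w < fs / 2))
  if (type %in% c("pass", "stop")) stopifnot(length(w) == 2L, w[1] < w[2])
  p <- butter_prototype(order)
  warped <- 2 * fs * tan(pi * w / fs)
  zpk <- switch(type,
    low  = lp2lp_zpk(p, 1, warped),
    high = {
      p_hp <- warped / p
      list(z = rep(0 + 0i, order), p = p_hp, k = Re(1 / prod(-p)))
    },
    pass = lp2bp_zpk(p, 1, sqrt(prod(warped)), diff(warped)),
    stop = lp2bs_zpk(p, 1, sqrt(prod(warped)), diff(warped)))
  dz <- bilinear_zpk(zpk$z, zpk$p, zpk$k, fs)
  structure(list(sos = zpk2sos(dz$z, dz$p, dz$k),
                 order = order, w = w, fs = fs, type = type),
            class = "sos_filter")
}

# causal filtering through cascaded biquads; x may be a vector or a
# matrix (series in columns, filtered independently).  The FIR numerator
# is applied by vector shifts; the recursive denominator by stats::filter
# (compiled loop), stripped of its ts attributes.
sos_filter_apply <- function(filt, x) {
  y <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1L)
  n <- nrow(y)
  for (i in seq_len(nrow(filt$sos))) {
    b <- filt$sos[i, 1:3]
    a <- filt$sos[i, 4:6]
    b <- b / a[1L]; a <- a / a[1L]
    v <- b[1L] * y
    if (n > 1L) v[-1L, ] <- v[-1L, , drop = FALSE] +
      b[2L] * y[-n, , drop = FALSE]
    if (n > 2L) v[-(1:2), ] <- v[-(1:2), , drop = FALSE] +
      b[3L] * y[-((n - 1L):n), , drop = FALSE]
    if (any(a[-1L] != 0)) {
      y <- stats::filter(v, -a[-1L], method = "recursive")
      y <- matrix(as.numeric(y), nrow = n)
    } else y <- v
  }
  if (is.matrix(x)) y else as.numeric(y)
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forwards and backwards so the net phase response is
#' zero and the magnitude response is squared.  Edges are protected by
#' odd-reflection padding.
#'
#' @param filt an `sos_filter` from [butter_filter()].
#' @param x numeric series, or a matrix with one series per column (all
#'   filtered independently).
#' @param padlen reflection padding length in samples; default 3 time
#'   constants of the lowest critical frequency, capped at the series
#'   length minus one.
#' @return filtered series (or matrix), same shape as `x`.
#' @export
filtfilt_sos <- function(filt, x, padlen = NULL) {
  M <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1L)
  n <- nrow(M)
  if (n < 4) stop("series too short to filter")
  if (is.null(padlen))
    padlen <- ceiling(3 * filt$fs / min(filt$w))
  padlen <- max(12L, min(n - 1L, as.integer(padlen)))
  front <- 2 * rep(M[1L, ], each = padlen) -
    M[(padlen + 1L):2L, , drop = FALSE]
  back <- 2 * rep(M[n, ], each = padlen) -
    M[(n - 1L):(n - padlen), , drop = FALSE]
  ext <- rbind(front, M, back)
  y <- sos_filter_apply(filt, ext)
  y <- sos_filter_apply(filt, y[nrow(y):1L, , drop = FALSE])
  y <- y[nrow(y):1L, , drop = FALSE][(padlen + 1L):(padlen + n), ,
                                     drop = FALSE]
  if (is.matrix(x)) y else as.numeric(y)
}
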