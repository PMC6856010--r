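# internal numerical helpers

# linear convolution of x with kernel h, truncated to length(x),
# computed via FFT in O(N log N)
fft_convolve_head <- function(x, h) {
  n <- length(x)
  m <- stats::nextn(n + length(h) - 1L, 2L)
  X <- stats::fft(c(x, rep(0, m - n)))
  H <- stats::fft(c(h, rep(0, m - length(h))))
  Re(stats::fft(X * H, inverse = TRUE))[seq_len(n)] / m
}

# polynomial coefficients (highest degree last, leading 1 first) from roots;
# imaginary residue discarded, so roots must come in conjugate pairs
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  Re(p)
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# evaluate expr under set.seed(seed) without disturbing the caller's RNG
# stream; seed = NULL uses (and advances) the ambient stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
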