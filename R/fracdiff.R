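#' Fractional differencing operator coefficients
#'
#' Binomial expansion coefficients of \eqn{(1-B)^d}, where \eqn{B} is the
#' backshift operator: \eqn{b_0 = 1}, \eqn{b_k = b_{k-1}(k-1-d)/k}.
#'
#' @param d fractional differencing parameter.
#' @param n number of coefficients to return.
#' @return numeric vector of length `n`.
#' @keywords internal
fracdiff_coefs <- function(d, n) {
  stopifnot(is_scalar_number(d), n >= 1L)
  b <- numeric(n)
  b[1L] <- 1
  if (n > 1L) {
    k <- seq_len(n - 1L)
    b[-1L] <- cumprod((k - 1 - d) / k)
  }
  b
}

#' Fast fractional differencing
#'
#' Applies \eqn{(1-B)^d} to a series by convolving it with the full-length
#' binomial coefficient sequence, using an FFT so the cost is
#' \eqn{O(N \log N)} rather than \eqn{O(N^2)}.  The series is treated as
#' zero before its first sample (type-II convention), so the output has the
#' same length as the input and `d = 1` reduces to the first difference with
#' the initial value retained.
#'
#' Differencing by the positive `d` of a long-memory process removes its
#' long-range temporal correlation; negative `d` fractionally integrates.
#'
#' @param x numeric series.
#' @param d fractional differencing parameter (any real; `0 <= d < 0.5`
#'   for removing stationary long memory, negative to integrate).
#' @return numeric series of the same length as `x`.
#' @seealso [fractional_integrate()]
#' @export
#' @examples
#' x <- rnorm(100)
#' all.equal(fractional_difference(x, 0), x)
#' all.equal(fractional_difference(x, 1), c(x[1], diff(x)))
fractional_difference <- function(x, d) {
  stopifnot(is.numeric(x), length(x) >= 1L, all(is.finite(x)),
            is_scalar_number(d))
  if (d == 0) return(as.numeric(x))
  fft_convolve_head(as.numeric(x), fracdiff_coefs(d, length(x)))
}

#' Fractional integration
#'
#' Inverse of [fractional_difference()]: applies \eqn{(1-B)^{-d}}.
#'
#' @inheritParams fractional_difference
#' @return numeric series of the same length as `x`.
#' @export
fractional_integrate <- function(x, d) {
  fractional_difference(x, -d)
}
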