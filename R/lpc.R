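# Linear predictive coding of band-limited EEG channels.  A channel is
# modelled as x_n = sum_i a_i x_{n-i} + e_n; the coefficient vector a_1..a_p
# is a compact encoding of the channel's spectral envelope and is the
# feature the affine-subspace index operates on.

#' Biased sample autocorrelation
#'
#' `r_k = (1/N) * sum_n x_n x_{n+k}` for `k = 0..max_lag`. The biased
#' (divide-by-N) estimator keeps the autocorrelation sequence positive
#' semi-definite, which guarantees a stable Levinson-Durbin recursion.
#' No mean removal is applied here; the conditioning chain removes the mean
#' before encoding.
#'
#' @param x Numeric vector.
#' @param max_lag Largest lag, strictly less than `length(x)`.
#' @return Numeric vector `c(r_0, ..., r_max_lag)`.
#' @export
autocorr_biased <- function(x, max_lag) {
  check_finite_numeric(x, "x")
  n <- length(x)
  if (max_lag >= n) stop_leapd("max_lag (%d) must be < length(x) (%d)",
                               max_lag, n)
  # FFT-based linear autocorrelation: zero-pad to avoid circular wrap.
  nfft <- stats::nextn(2L * n, 2L)
  X <- fft(c(x, numeric(nfft - n)))
  ac <- Re(fft(Mod(X)^2, inverse = TRUE)) / nfft
  ac[seq_len(max_lag + 1L)] / n
}

#' Levinson-Durbin recursion
#'
#' Solves the Yule-Walker normal equations `R a = r` for a Toeplitz
#' autocorrelation matrix in O(p^2), returning predictor coefficients
#' (convention `x_hat_n = sum_i a_i x_{n-i}`) and the final prediction-error
#' variance.
#'
#' @param r Autocorrelation sequence `c(r_0, ..., r_p)` (or longer).
#' @param order Model order p.
#' @return List with `coefficients` (length p) and `error_variance`.
#' @export
levinson_durbin <- function(r, order) {
  check_finite_numeric(r, "r")
  if (length(r) < order + 1L) {
    stop_leapd("need r_0..r_%d (%d values), got %d", order, order + 1L,
               length(r))
  }
  if (r[1L] <= 0) stop_leapd("r_0 must be positive, got %s", r[1L])
  if (order == 0L) {
    return(list(coefficients = numeric(0), error_variance = r[1L]))
  }
  a <- numeric(order)
  err <- r[1L]
  for (m in seq_len(order)) {
    acc <- r[m + 1L]
    if (m > 1L) acc <- acc - sum(a[seq_len(m - 1L)] * r[m:2L])
    k <- acc / err
    if (!is.finite(k) || abs(k) >= 1 + 1e-10) {
      stop_leapd(paste("autocorrelation sequence is not positive definite",
                       "at order %d (reflection coefficient %.6g);",
                       "unstable recursion"), m, k)
    }
    a_new <- a
    a_new[m] <- k
    if (m > 1L) {
      a_new[seq_len(m - 1L)] <- a[seq_len(m - 1L)] - k * a[(m - 1L):1L]
    }
    a <- a_new
    err <- err * (1 - k^2)
    if (err <= 0) {
      stop_leapd("prediction-error variance collapsed at order %d", m)
    }
  }
  list(coefficients = a, error_variance = err)
}

#' Encode one channel as an LPC coefficient vector
#'
#' Applies the full conditioning chain (line-noise notch, zero-phase
#' band-pass to `bd`, unit-power normalization) and fits an order-`order`
#' autoregressive model to the whole record by the autocorrelation method.
#' One recording is one analysis frame: no windowing or segmentation.
#'
#' @param x Numeric vector (one channel, full recording).
#' @param sample_rate Sampling rate in Hz.
#' @param bd Analysis [band()].
#' @param order LPC order p (default 10).
#' @param line_freq Notch frequency in Hz, or `NULL` to skip the notch
#'   (default 60).
#' @param channel Optional channel label carried on the result.
#' @return An object of class `lpc_vector`: list with `order`,
#'   `coefficients`, `error_variance`, `band`, `channel`.
#' @export
lpc_encode <- function(x, sample_rate, bd, order = 10, line_freq = 60,
                       channel = NA_character_) {
  check_scalar(order, "order", 1, Inf)
  order <- as.integer(order)
  if (length(x) <= order + 1L) {
    stop_leapd("recording too short (%d samples) for LPC order %d",
               length(x), order)
  }
  bd <- check_band(bd, sample_rate)
  y <- condition_channel(x, sample_rate, bd, line_freq)
  r <- autocorr_biased(y, order)
  fit <- levinson_durbin(r, order)
  structure(
    list(order = order, coefficients = fit$coefficients,
         error_variance = fit$error_variance, band = bd, channel = channel),
    class = "lpc_vector"
  )
}

#' @export
print.lpc_vector <- function(x, ...) {
  cat(sprintf("<LPC order %d, band %g-%g Hz, channel %s, sigma^2 %.4g>\n",
              x$order, x$band$f_lo, x$band$f_hi, x$channel,
              x$error_variance))
  invisible(x)
}

#' All-pole spectrum of an LPC model
#'
#' `S(f) = sigma^2 / |1 - sum_k a_k exp(-i 2 pi f k / fs)|^2`, the power
#' spectral density implied by the fitted autoregressive model (up to the
#' sampling-rate density constant).
#'
#' @param v An `lpc_vector`, or a plain list with `coefficients` and
#'   `error_variance`.
#' @param sample_rate Sampling rate in Hz.
#' @param freqs Frequencies (Hz) at which to evaluate, within
#'   `[0, sample_rate]`.
#' @return Numeric vector of spectral values at `freqs`.
#' @export
lpc_spectrum <- function(v, sample_rate, freqs) {
  check_finite_numeric(freqs, "freqs")
  a <- v$coefficients
  s2 <- v$error_variance
  if (length(a) == 0L) return(rep(s2, length(freqs)))
  k <- seq_along(a)
  vapply(freqs, function(f) {
    den <- 1 - sum(a * exp(-2i * pi * f * k / sample_rate))
    s2 / Mod(den)^2
  }, numeric(1))
}
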