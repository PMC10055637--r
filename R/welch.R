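# Welch power spectral density estimation, used by the spectral baselines
# and by the synthetic-cohort checks.  Hann-windowed overlapping segments,
# one-sided density scaling.

#' Welch power spectral density
#'
#' Averaged modified periodogram with a Hann window. Defaults give 0.5 Hz
#' resolution at 500 Hz sampling (2 s segments, 50% overlap), appropriate
#' for minutes-long resting-state recordings.
#'
#' @param x Numeric vector.
#' @param sample_rate Sampling rate in Hz.
#' @param seg_seconds Segment length in seconds (default 2).
#' @param overlap Fractional overlap between segments in [0, 1) (default 0.5).
#' @param demean Remove the segment mean before windowing (default TRUE).
#' @return A list with `freq` (Hz, one-sided) and `psd` (power per Hz);
#'   for a unit-power signal the PSD integrates to about 1.
#' @export
welch_psd <- function(x, sample_rate, seg_seconds = 2, overlap = 0.5,
                      demean = TRUE) {
  check_finite_numeric(x, "x")
  check_scalar(sample_rate, "sample_rate")
  check_scalar(overlap, "overlap", 0, 0.999)
  nper <- round(seg_seconds * sample_rate)
  n <- length(x)
  if (nper > n) nper <- n
  if (nper < 8L) stop_leapd("segment too short (%d samples)", nper)
  step <- max(1L, floor(nper * (1 - overlap)))
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / nper)  # periodic Hann
  scale <- 1 / (sample_rate * sum(w^2))
  nfreq <- nper %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    if (demean) seg <- seg - mean(seg)
    X <- fft(seg * w)
    acc <- acc + (Mod(X[seq_len(nfreq)])^2) * scale
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nper is even)
  dbl <- rep(2, nfreq)
  dbl[1L] <- 1
  if (nper %% 2L == 0L) dbl[nfreq] <- 1
  list(freq = (seq_len(nfreq) - 1L) * sample_rate / nper, psd = psd * dbl)
}

# Integrated PSD over [f_lo, f_hi] (trapezoidal).
band_power_from_psd <- function(freq, psd, f_lo, f_hi) {
  sel <- freq >= f_lo & freq <= f_hi
  if (sum(sel) < 2L) return(0)
  f <- freq[sel]; p <- psd[sel]
  sum(diff(f) * (head(p, -1) + p[-1]) / 2)
}

# Frequency of the PSD maximum inside [f_lo, f_hi].
peak_frequency <- function(x, sample_rate, f_lo, f_hi, ...) {
  w <- welch_psd(x, sample_rate, ...)
  sel <- w$freq >= f_lo & w$freq <= f_hi
  w$freq[sel][which.max(w$psd[sel])]
}
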