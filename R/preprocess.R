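# Per-channel signal conditioning: line-noise notch, zero-phase band-pass,
# unit-power normalization, truncation.  Composition order for the index
# pipeline is notch -> band-pass -> normalize, so every encoded signal has
# unit mean-square power regardless of band.

#' Frequency band
#'
#' A half-open analysis band in Hz. Validity against a concrete sampling rate
#' (f_hi below Nyquist) is checked at use time by the filtering functions.
#'
#' @param f_lo Lower edge in Hz, strictly positive.
#' @param f_hi Upper edge in Hz, strictly greater than `f_lo`.
#' @return An object of class `leapd_band`.
#' @examples
#' band(8, 13)  # alpha
#' @export
band <- function(f_lo, f_hi) {
  check_scalar(f_lo, "f_lo")
  check_scalar(f_hi, "f_hi")
  if (f_lo <= 0) stop_leapd("f_lo must be > 0, got %s", f_lo)
  if (f_hi <= f_lo) stop_leapd("f_hi (%s) must exceed f_lo (%s)", f_hi, f_lo)
  structure(list(f_lo = f_lo, f_hi = f_hi), class = "leapd_band")
}

#' @export
print.leapd_band <- function(x, ...) {
  cat(sprintf("<band %g-%g Hz>\n", x$f_lo, x$f_hi))
  invisible(x)
}

check_band <- function(b, sample_rate) {
  if (!inherits(b, "leapd_band")) b <- band(b[[1]], b[[2]])
  if (b$f_hi >= sample_rate / 2) {
    stop_leapd("band upper edge %g Hz is not below Nyquist (%g Hz)",
               b$f_hi, sample_rate / 2)
  }
  b
}

#' Normalize a time series to unit power
#'
#' Removes the mean, then rescales so the mean squared value equals 1.
#' Normalization is the last conditioning step before LPC encoding, so the
#' encoder sees the same power on every channel and band.
#'
#' @param x Numeric vector, length >= 2, all finite.
#' @return Numeric vector of the same length with zero mean and unit
#'   mean-square.
#' @export
normalize_unit_power <- function(x) {
  check_finite_numeric(x, "x")
  if (length(x) < 2L) stop_leapd("x must have length >= 2")
  x <- x - mean(x)
  ms <- mean(x^2)
  if (ms <= .Machine$double.eps * 100) {
    stop_leapd("signal has zero variance after mean removal; cannot normalize")
  }
  x / sqrt(ms)
}

# Zero-phase filtering with reflect padding.  signal::filtfilt alone leaves
# visible startup transients for low cut-off IIR filters on long records;
# reflecting one filter-response length of samples at each end suppresses
# them.
filtfilt_padded <- function(filt, x, pad_len) {
  n <- length(x)
  pad_len <- min(pad_len, n - 1L)
  if (pad_len > 0L) {
    left  <- 2 * x[1L] - x[(pad_len + 1L):2L]
    right <- 2 * x[n]  - x[(n - 1L):(n - pad_len)]
    xp <- c(left, x, right)
    y <- signal::filtfilt(filt, xp)
    y[(pad_len + 1L):(pad_len + n)]
  } else {
    signal::filtfilt(filt, x)
  }
}

#' Remove power-line noise with a narrow notch
#'
#' Second-order IIR notch (constrained-pole biquad) at the line frequency,
#' quality factor `q`, applied forward and backward so the net response has
#' zero phase.
#'
#' @param x Numeric vector.
#' @param sample_rate Sampling rate in Hz.
#' @param line_freq Line frequency in Hz (default 60).
#' @param q Notch quality factor, centre frequency over -3 dB bandwidth
#'   (default 35: a 60 Hz notch about 1.7 Hz wide).
#' @return Filtered vector, same length as `x`.
#' @export
notch_line <- function(x, sample_rate, line_freq = 60, q = 35) {
  check_finite_numeric(x, "x")
  check_scalar(sample_rate, "sample_rate")
  check_scalar(line_freq, "line_freq")
  if (line_freq >= sample_rate / 2) {
    stop_leapd("line_freq %g Hz must be below Nyquist (%g Hz)",
               line_freq, sample_rate / 2)
  }
  w0 <- 2 * pi * line_freq / sample_rate
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  filt <- signal::Arma(b = b, a = a)
  # transient scale ~ Q cycles of the notch frequency
  pad <- ceiling(3 * q * sample_rate / line_freq)
  filtfilt_padded(filt, x, pad)
}

#' Zero-phase Butterworth band-pass
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (zero phase, squared magnitude response), with reflect padding at the
#' edges to suppress startup transients.
#'
#' @param x Numeric vector.
#' @param sample_rate Sampling rate in Hz.
#' @param bd A [band()] (or 2-element list) valid for `sample_rate`.
#' @param order Butterworth order of the underlying one-pass filter
#'   (default 4).
#' @return Filtered vector, same length as `x`.
#' @export
bandpass_zero_phase <- function(x, sample_rate, bd, order = 4) {
  check_finite_numeric(x, "x")
  check_scalar(sample_rate, "sample_rate")
  bd <- check_band(bd, sample_rate)
  w <- c(bd$f_lo, bd$f_hi) / (sample_rate / 2)
  filt <- signal::butter(order, w, type = "pass")
  # transient scale set by the low edge of the band
  pad <- ceiling(3 * sample_rate / bd$f_lo)
  filtfilt_padded(filt, x, pad)
}

#' Keep the leading fraction of a recording
#'
#' Truncation used by the robustness sweep: the first
#' `floor(fraction * N)` samples are retained.
#'
#' @param x Numeric vector.
#' @param fraction Fraction of samples to keep, in (0, 1].
#' @return The truncated vector (`x` itself when `fraction == 1`).
#' @export
truncate_fraction <- function(x, fraction) {
  check_scalar(fraction, "fraction")
  if (fraction <= 0 || fraction > 1) {
    stop_leapd("fraction must be in (0, 1], got %s", fraction)
  }
  if (fraction == 1) return(x)
  n_keep <- floor(fraction * length(x))
  if (n_keep < 2L) stop_leapd("truncation to %s leaves fewer than 2 samples",
                              fraction)
  x[seq_len(n_keep)]
}

# The fixed conditioning chain feeding the LPC encoder.
condition_channel <- function(x, sample_rate, bd, line_freq = 60) {
  if (!is.null(line_freq)) x <- notch_line(x, sample_rate, line_freq)
  x <- bandpass_zero_phase(x, sample_rate, bd)
  normalize_unit_power(x)
}
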