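# Seeded synthetic resting-state EEG cohorts.  Each subject carries a latent
# cognition level c in [0, 1]; on informative channels the dominant
# oscillation shifts from theta toward alpha as c rises and a beta-band
# oscillation gains amplitude, on top of 1/f background and white noise.
# Non-informative channels carry background and noise only.  This encodes
# the spectral structure the index is designed to detect: a theta-to-alpha
# peak shift and a beta-power increase with better cognition.

DEFAULT_INFORMATIVE <- c("P8", "PO7", "CP1", "CP2", "P6", "O2", "P4", "F4")
DEFAULT_CHANNELS <- c(DEFAULT_INFORMATIVE,
                      c("Fp1", "Fz", "F3", "C3", "C4", "T7", "T8", "O1"))

#' Specification of a synthetic EEG cohort
#'
#' Bundles every knob of the generator. Defaults encode a cohort in which
#' the informative-channel spectral peak moves from 6.5 Hz (theta, worst
#' cognition) to 10.5 Hz (alpha, best cognition) and the 20 Hz beta
#' oscillation grows from gain 0.5 to 1.5, over a 1/f background of unit
#' amplitude with additive white noise.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_channels Number of channels (default 16).
#' @param channel_labels Channel labels; defaults to 10-10 names.
#' @param informative_channels Subset of labels carrying the cognition
#'   effect (default: 8 centro-parietal/occipital labels).
#' @param sample_rate Sampling rate in Hz (default 500).
#' @param duration Recording length in seconds (default 160).
#' @param peak_lo,peak_hi Endpoints in Hz of the theta-to-alpha peak
#'   trajectory `f_peak(c) = peak_lo + c (peak_hi - peak_lo)`
#'   (defaults 6.5, 10.5). Setting `peak_lo == peak_hi` freezes the peak.
#' @param beta_center Beta oscillation frequency in Hz (default 20).
#' @param beta_gain_lo,beta_gain_hi Beta amplitude multipliers at c = 0 and
#'   c = 1 (defaults 0.5, 1.5). Equal values freeze the beta effect.
#' @param aperiodic_exponent Log-log slope magnitude of the 1/f background
#'   over 2-40 Hz (default 1).
#' @param aperiodic_gain Amplitude of the 1/f background (default 1).
#' @param peak_gain Amplitude of the shifting oscillation (default 1).
#' @param noise_sd White-noise amplitude (default 0.5).
#' @param score_min,score_max Integer range of the MoCA-like score
#'   (defaults 10, 30).
#' @param age_range Age range in years, sampled uniformly (default 55-80).
#' @param age_latent_correlation Gaussian-copula correlation between age and
#'   the latent cognition level (default 0: ages independent of c, so
#'   age-controlled correlation is exercised but not confounded).
#' @param pd_fraction Probability a subject is labelled "PD" rather than
#'   "control" (default 2/3, a 2:1 ratio), independent of c.
#' @param seed Integer seed governing the whole cohort.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 60,
                           n_channels = 16,
                           channel_labels = NULL,
                           informative_channels = NULL,
                           sample_rate = 500,
                           duration = 160,
                           peak_lo = 6.5, peak_hi = 10.5,
                           beta_center = 20,
                           beta_gain_lo = 0.5, beta_gain_hi = 1.5,
                           aperiodic_exponent = 1.0,
                           aperiodic_gain = 1.0,
                           peak_gain = 1.0,
                           noise_sd = 0.5,
                           score_min = 10, score_max = 30,
                           age_range = c(55, 80),
                           age_latent_correlation = 0,
                           pd_fraction = 2 / 3,
                           seed = 1) {
  check_scalar(n_subjects, "n_subjects", 1, Inf)
  check_scalar(n_channels, "n_channels", 1, Inf)
  if (is.null(channel_labels)) {
    channel_labels <- if (n_channels <= length(DEFAULT_CHANNELS)) {
      DEFAULT_CHANNELS[seq_len(n_channels)]
    } else {
      c(DEFAULT_CHANNELS,
        sprintf("X%02d", seq_len(n_channels - length(DEFAULT_CHANNELS))))
    }
  }
  if (length(channel_labels) != n_channels) {
    stop_leapd("channel_labels length %d != n_channels %d",
               length(channel_labels), n_channels)
  }
  if (is.null(informative_channels)) {
    informative_channels <- intersect(DEFAULT_INFORMATIVE, channel_labels)
    if (length(informative_channels) == 0L) {
      informative_channels <- channel_labels[seq_len(min(8L, n_channels))]
    }
  }
  if (!all(informative_channels %in% channel_labels)) {
    stop_leapd("informative_channels must be a subset of channel_labels")
  }
  if (peak_lo > peak_hi) stop_leapd("peak_lo must be <= peak_hi")
  if (peak_hi >= sample_rate / 2 || peak_lo <= 0) {
    stop_leapd("peak frequencies must lie in (0, Nyquist)")
  }
  n_samples <- duration * sample_rate
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    stop_leapd("duration * sample_rate must be a whole number of samples")
  }
  check_scalar(age_latent_correlation, "age_latent_correlation", -1, 1)
  check_scalar(pd_fraction, "pd_fraction", 0, 1)
  if (score_min >= score_max) stop_leapd("score_min must be < score_max")
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_channels = as.integer(n_channels),
         channel_labels = channel_labels,
         informative_channels = informative_channels,
         sample_rate = sample_rate, duration = duration,
         peak_lo = peak_lo, peak_hi = peak_hi,
         beta_center = beta_center,
         beta_gain_lo = beta_gain_lo, beta_gain_hi = beta_gain_hi,
         aperiodic_exponent = aperiodic_exponent,
         aperiodic_gain = aperiodic_gain, peak_gain = peak_gain,
         noise_sd = noise_sd,
         score_min = as.integer(score_min),
         score_max = as.integer(score_max),
         age_range = age_range,
         age_latent_correlation = age_latent_correlation,
         pd_fraction = pd_fraction,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Unit-variance AR(2) resonator: white noise through complex-conjugate poles
# at radius 0.97 and the target frequency.
ar2_resonator <- function(n, freq, sample_rate, radius = 0.97) {
  theta <- 2 * pi * freq / sample_rate
  y <- stats::filter(rnorm(n), c(2 * radius * cos(theta), -radius^2),
                     method = "recursive")
  y <- as.numeric(y)
  y / sd(y)
}

# Unit-variance 1/f^alpha background by spectral shaping of white noise:
# scale FFT amplitudes by f^(-alpha/2) (flat below 1 Hz to bound the DC
# region), keeping Hermitian symmetry so the inverse transform is real.
one_over_f_noise <- function(n, sample_rate, exponent) {
  w <- rnorm(n)
  X <- fft(w)
  freqs <- seq_len(n) - 1L
  freqs <- pmin(freqs, n - freqs) * sample_rate / n
  amp <- pmax(freqs, 1)^(-exponent / 2)
  amp[1L] <- 0
  y <- Re(fft(X * amp, inverse = TRUE)) / n
  y / sd(y)
}

#' Generate one synthetic subject recording
#'
#' Deterministic given `(c, spec, subject_seed)`. Informative channels carry
#' a theta-alpha resonator at `f_peak(c)`, a beta resonator scaled by the
#' c-dependent gain, the 1/f background, and white noise; other channels
#' carry background and noise only.
#'
#' @param c Latent cognition level in [0, 1].
#' @param spec A [synthetic_spec()].
#' @param subject_seed Integer seed for this subject's noise streams.
#' @return An [eeg_recording()].
#' @export
generate_subject <- function(c, spec, subject_seed) {
  if (!inherits(spec, "synthetic_spec")) stop_leapd("spec must be a synthetic_spec")
  check_scalar(c, "c", 0, 1)
  n <- as.integer(round(spec$duration * spec$sample_rate))
  f_peak <- spec$peak_lo + c * (spec$peak_hi - spec$peak_lo)
  beta_gain <- spec$beta_gain_lo + c * (spec$beta_gain_hi - spec$beta_gain_lo)
  informative <- spec$channel_labels %in% spec$informative_channels
  samples <- withr::with_seed(as.integer(subject_seed), {
    m <- matrix(0, nrow = spec$n_channels, ncol = n)
    for (ch in seq_len(spec$n_channels)) {
      x <- spec$aperiodic_gain *
        one_over_f_noise(n, spec$sample_rate, spec$aperiodic_exponent) +
        spec$noise_sd * rnorm(n)
      if (informative[ch]) {
        x <- x + spec$peak_gain * ar2_resonator(n, f_peak, spec$sample_rate) +
          beta_gain * ar2_resonator(n, spec$beta_center, spec$sample_rate)
      }
      m[ch, ] <- x
    }
    m
  })
  eeg_recording(subject_id = sprintf("c%.3f", c),
                channel_labels = spec$channel_labels,
                sample_rate = spec$sample_rate,
                samples = samples)
}

#' Map a latent cognition level to a MoCA-like integer score
#'
#' `round(score_min + c (score_max - score_min))`, clipped to the score
#' range: monotone, integer-valued, MoCA-like.
#'
#' @param c Latent level(s) in [0, 1]; vectorized.
#' @param spec A [synthetic_spec()].
#' @return Integer score(s) in `[score_min, score_max]`.
#' @export
latent_to_score <- function(c, spec) {
  if (any(c < 0 | c > 1)) stop_leapd("c must lie in [0, 1]")
  s <- round(spec$score_min + c * (spec$score_max - spec$score_min))
  as.integer(pmin(pmax(s, spec$score_min), spec$score_max))
}

#' Generate a full synthetic cohort
#'
#' Draws per-subject latent levels uniformly on [0, 1], ages (by default
#' independent of cognition), PD/control labels at `pd_fraction`, and one
#' recording per subject. Fully reproducible from `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_cohort` with `recordings` (named list
#'   of [eeg_recording()]), `subjects` (data.frame: id, group, age, moca),
#'   and `latents` (named vector of c values).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop_leapd("spec must be a synthetic_spec")
  if (spec$n_subjects < 2L) stop_leapd("need at least 2 subjects")
  ns <- spec$n_subjects
  draws <- withr::with_seed(spec$seed, {
    c_lat <- runif(ns)
    z_c <- stats::qnorm(pmin(pmax(c_lat, 1e-12), 1 - 1e-12))
    rho <- spec$age_latent_correlation
    z_a <- rho * z_c + sqrt(1 - rho^2) * rnorm(ns)
    age <- spec$age_range[1] +
      diff(spec$age_range) * stats::pnorm(z_a)
    group <- ifelse(runif(ns) < spec$pd_fraction, "PD", "control")
    list(c_lat = c_lat, age = age, group = group)
  })
  ids <- sprintf("S%03d", seq_len(ns))
  recordings <- vector("list", ns)
  names(recordings) <- ids
  for (i in seq_len(ns)) {
    rec <- generate_subject(draws$c_lat[i], spec, derive_seed(spec$seed, i))
    rec$subject_id <- ids[i]
    recordings[[i]] <- rec
  }
  subjects <- data.frame(
    id = ids,
    group = draws$group,
    age = round(draws$age, 1),
    moca = latent_to_score(draws$c_lat, spec),
    stringsAsFactors = FALSE
  )
  latents <- draws$c_lat
  names(latents) <- ids
  structure(list(recordings = recordings, subjects = subjects,
                 latents = latents, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic cohort: %d subjects, %d channels, %g s @ %g Hz>\n",
              length(x$recordings), x$spec$n_channels, x$spec$duration,
              x$spec$sample_rate))
  invisible(x)
}

#' Convert a synthetic cohort to an analysis dataset
#'
#' @param cohort A `synthetic_cohort`.
#' @return A `leapd_dataset` (see [leapd_dataset()]).
#' @export
cohort_dataset <- function(cohort) {
  leapd_dataset(subjects = cohort$subjects, recordings = cohort$recordings)
}
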