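# Shared fixture builders.  All fixtures are generated in code at test time.

# A small, fast synthetic cohort for structural tests.
tiny_cohort <- function(n_subjects = 16, duration = 10, seed = 5, ...) {
  generate_cohort(synthetic_spec(n_subjects = n_subjects,
                                 duration = duration, seed = seed, ...))
}

# Pure sinusoid helper.
tone <- function(freq, sample_rate = 500, seconds = 10, phase = 0) {
  t <- seq(0, seconds - 1 / sample_rate, by = 1 / sample_rate)
  sin(2 * pi * freq * t + phase)
}

# Random stable AR autocorrelation: biased acf of a realization of a random
# stable AR process (positive definite by construction).
random_ar_acf <- function(max_lag, n = 400, ar_order = NULL) {
  ar_order <- ar_order %||% sample(1:4, 1)
  # random reflection coefficients strictly inside (-1, 1) -> stable AR
  refl <- runif(ar_order, -0.9, 0.9)
  a <- numeric(0)
  for (k in refl) a <- c(a - k * rev(a), k)        # step-up recursion
  x <- as.numeric(stats::filter(rnorm(n), a, method = "recursive"))
  autocorr_biased(x, max_lag)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal EDF writer (16-bit continuous, one data record per second),
# used only to exercise the EDF reader against independently constructed
# bytes.
write_tiny_edf <- function(path, samples, labels, sample_rate,
                           phys_range = c(-200, 200)) {
  ns <- nrow(samples)
  n_rec <- ncol(samples) / sample_rate
  stopifnot(n_rec == round(n_rec))
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeBin(charToRaw(pad(x, w)), con)
  wr("0", 8); wr("test patient", 80); wr("test recording", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256 * (1 + ns), 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  for (l in labels) wr(l, 16)
  for (i in 1:ns) wr("", 80)           # transducer
  for (i in 1:ns) wr("uV", 8)          # dimension
  for (i in 1:ns) wr(phys_range[1], 8)
  for (i in 1:ns) wr(phys_range[2], 8)
  for (i in 1:ns) wr(-32768, 8)
  for (i in 1:ns) wr(32767, 8)
  for (i in 1:ns) wr("", 80)           # prefiltering
  for (i in 1:ns) wr(sample_rate, 8)
  for (i in 1:ns) wr("", 32)
  gain <- (phys_range[2] - phys_range[1]) / (32767 - (-32768))
  dig <- round((samples - phys_range[1]) / gain) - 32768
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * sample_rate + 1):(r * sample_rate)
    for (s in seq_len(ns)) {
      writeBin(as.integer(dig[s, cols]), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

# Minimal BrainVision writer (IEEE float32 multiplexed).
write_tiny_brainvision <- function(stem, samples, labels, sample_rate) {
  vhdr <- paste0(stem, ".vhdr")
  eeg <- paste0(stem, ".eeg")
  lines <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    sprintf("DataFile=%s", basename(eeg)),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nrow(samples)),
    sprintf("SamplingInterval=%g", 1e6 / sample_rate),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nrow(samples)), labels)
  )
  writeLines(lines, vhdr)
  con <- file(eeg, "wb")
  writeBin(as.numeric(samples), con, size = 4, endian = "little")
  close(con)
  invisible(vhdr)
}
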