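# Internal helpers shared across modules.

#' @importFrom stats fft rnorm runif median sd cor pt pchisq logLik lm
#'   wilcox.test quantile
#' @importFrom utils head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_leapd <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

check_finite_numeric <- function(x, what) {
  if (!is.numeric(x)) stop_leapd("%s must be numeric", what)
  if (any(!is.finite(x))) stop_leapd("%s contains non-finite values", what)
  invisible(x)
}

check_scalar <- function(x, what, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_leapd("%s must be a finite numeric scalar", what)
  }
  if (x < lo || x > hi) {
    stop_leapd("%s must be in [%s, %s], got %s", what, lo, hi, x)
  }
  invisible(x)
}

# Derive a bounded positive integer seed from a base seed and a stream index,
# staying well inside the 32-bit integer range.
derive_seed <- function(seed, index) {
  base <- as.numeric(seed) %% 1000003
  as.integer((base * 2003 + as.numeric(index) * 7919) %% 2147483647L)
}

# Mid-rank transform (ties get average ranks), the rank convention used by
# every rank statistic in the package.
midranks <- function(x) rank(x, ties.method = "average")
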