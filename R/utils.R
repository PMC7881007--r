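#' @importFrom stats approx fft rnorm runif splinefun sd quantile IQR
#' @importFrom rlang abort warn
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) x * (x > 0)

#' Dominant frequency of a series
#'
#' Frequency (Hz) of the largest periodogram ordinate over strictly positive
#' frequencies, computed by FFT. Used to assign intrinsic mode functions to
#' signal or noise bands.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @return frequency in Hz (scalar).
#' @export
dominant_freq <- function(x, fs) {
  n <- length(x)
  if (n < 4) abort("series too short for a dominant-frequency estimate")
  x <- x - mean(x)
  p <- Mod(fft(x))[seq_len(n %/% 2 + 1)]
  p[1] <- 0 # exclude DC
  k <- which.max(p)
  (k - 1) * fs / n
}

moving_average <- function(x, n) {
  if (n <= 1) return(x)
  cs <- cumsum(c(0, x))
  half <- n %/% 2
  idx <- seq_along(x)
  lo <- pmax(idx - half, 1)
  hi <- pmin(idx + (n - 1 - half), length(x))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# run code under a fixed RNG seed without disturbing the caller's stream;
# seed = NULL leaves the current stream untouched.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), force(code))
}

check_prob <- function(p) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
    abort("`p` must be a single probability in [0, 1]")
  p
}
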