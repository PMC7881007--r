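#' Pearson correlation by raw sums
#'
#' Measures information loss between a series and its denoised version with
#' the raw-sum form of the Pearson coefficient,
#' \deqn{r = \frac{\sum XY - \sum X \sum Y / N}
#'   {\sqrt{(\sum X^2 - (\sum X)^2/N)(\sum Y^2 - (\sum Y)^2/N)}}.}
#'
#' @param x,y equal-length numeric series (N >= 2), neither constant.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) abort("x and y must have equal length")
  if (n < 2) abort("need at least 2 samples")
  sx <- sum(x); sy <- sum(y)
  den2 <- (sum(x^2) - sx^2 / n) * (sum(y^2) - sy^2 / n)
  if (den2 <= 0) abort("constant series: Pearson correlation undefined")
  (sum(x * y) - sx * sy / n) / sqrt(den2)
}

#' Retention gate on denoised records
#'
#' A record survives filtering only if the Pearson correlation between the
#' original and denoised series is strictly greater than `threshold`
#' (default 0.93), limiting the information loss the denoiser may introduce.
#'
#' @param original,denoised equal-length series.
#' @param threshold retention threshold (strict inequality).
#' @return logical `keep`, with the correlation attached as attribute
#'   `"pearson"`.
#' @export
retention_filter <- function(original, denoised, threshold = 0.93) {
  r <- pearson_cor(original, denoised)
  structure(r > threshold, pearson = r)
}

#' EMD-based denoising by dominant-frequency band selection
#'
#' Decomposes the signal with [emd()], estimates each IMF's dominant frequency
#' by FFT periodogram argmax, and reconstructs from exactly those IMFs whose
#' dominant frequency lies inside `band` (default 0.4-20 Hz: the pulse band
#' 0.5-2 Hz plus harmonics, excluding respiration wander below 0.3 Hz,
#' powerline 50/60 Hz and instrument noise above 90 Hz). The residue carries
#' baseline drift and is dropped unless `keep_residue = TRUE`.
#'
#' @param record a `signal_record`, or a numeric series (then `fs` required).
#' @param band `c(f_lo, f_hi)` in Hz.
#' @param fs sampling rate (taken from the record when omitted).
#' @param keep_residue also add the residue when its dominant frequency lies
#'   in band (default `FALSE`).
#' @param ... passed to [emd()].
#' @return denoised numeric series of the input length.
#' @export
denoise <- function(record, band = c(0.4, 20), fs = NULL,
                    keep_residue = FALSE, ...) {
  if (inherits(record, "signal_record")) {
    x <- record$samples
    fs <- record$fs
  } else {
    x <- record
    if (is.null(fs)) abort("fs must be supplied for a bare series")
  }
  dec <- emd(x, ...)
  if (length(dec$imfs) == 0) abort("no IMFs extracted: unusable record")
  fr <- vapply(dec$imfs, dominant_freq, 0, fs = fs)
  keep <- fr >= band[1] & fr <= band[2]
  if (!any(keep)) abort("all IMFs rejected by the frequency band: unusable record")
  y <- Reduce(`+`, dec$imfs[keep])
  if (keep_residue) {
    rf <- tryCatch(dominant_freq(dec$residue, fs), error = function(e) NA_real_)
    if (!is.na(rf) && rf >= band[1] && rf <= band[2]) y <- y + dec$residue
  }
  y
}

# prominence of each candidate trough: depth below the lower of the two
# highest barriers separating it from a deeper trough (computed on -x as the
# standard peak-prominence definition)
trough_prominence <- function(x, idx) {
  y <- -x
  n <- length(x)
  vapply(idx, function(i) {
    h <- y[i]
    # walk left until a higher point than y[i]; barrier is the min in between
    left <- if (i > 1) {
      j <- which(y[seq_len(i - 1)] > h)
      lo <- if (length(j)) max(j) + 1 else 1
      min(y[lo:(i - 1)], h)
    } else h
    right <- if (i < n) {
      j <- which(y[(i + 1):n] > h)
      hi <- if (length(j)) i + min(j) - 1 else n
      min(y[(i + 1):hi], h)
    } else h
    h - max(left, right)
  }, 0)
}

# beat period in samples, from the autocorrelation peak in the plausible
# heart-rate lag range
estimate_period <- function(sm, fs, hr_min_bpm = 40, hr_max_bpm = 180) {
  lag_lo <- max(2L, floor(fs * 60 / hr_max_bpm))
  lag_hi <- min(length(sm) - 2L, ceiling(fs * 60 / hr_min_bpm))
  if (lag_hi <= lag_lo) abort("record too short to estimate a beat period")
  ac <- stats::acf(sm, lag.max = lag_hi, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  lags <- lag_lo:lag_hi
  lags[which.max(ac[lags + 1])]
}

#' Trough-based beat segmentation
#'
#' Divides a (denoised) pulse wave into cycles running from valley to valley,
#' using the main (systolic) wave peaks as the reference: the beat period is
#' first estimated from the autocorrelation of a mildly smoothed copy
#' (5-point moving average); local maxima are then thinned greedily by height
#' under a minimum separation of 0.55 period, which keeps exactly the
#' systolic peak of each beat (reflected and dicrotic peaks sit well within
#' the separation of their own systolic peak); the trough closing each cycle
#' is the minimum between consecutive systolic peaks, and the minimum before
#' the first peak opens the first cycle. The partial beat after the last peak
#' has no closing valley and is dropped, so k detected beats yield k - 1
#' trough-to-trough intervals.
#'
#' @param x numeric series (>= 2 beats long).
#' @param fs sampling rate in Hz.
#' @param smooth_n moving-average width in samples (default 5).
#' @param hr_min_bpm,hr_max_bpm plausible heart-rate range bounding the
#'   period search (defaults 40 and 180).
#' @return tibble with 0-based half-open intervals: columns `start`, `end`
#'   (one row per full beat), plus attribute `"troughs"` (0-based indices).
#' @export
segment_beats <- function(x, fs, smooth_n = 5, hr_min_bpm = 40,
                          hr_max_bpm = 180) {
  sm <- moving_average(x, smooth_n)
  ex <- find_extrema(sm)
  if (length(ex$maxima) < 2 || length(ex$minima) < 1)
    abort("fewer than 2 troughs: unsegmentable record")
  period <- estimate_period(sm, fs, hr_min_bpm, hr_max_bpm)
  min_sep <- 0.55 * period
  # systolic peaks stand near the top of the amplitude range; ripples on the
  # diastolic tail do not clear the midrange
  floor_h <- 0.5 * (quantile(sm, 0.99) + quantile(sm, 0.01))
  cand <- ex$maxima[sm[ex$maxima] >= floor_h]
  if (length(cand) < 2) abort("fewer than 2 troughs: unsegmentable record")
  cand <- cand[order(sm[cand], decreasing = TRUE)]
  peaks <- integer(0)
  for (p in cand) {
    if (all(abs(p - peaks) >= min_sep)) peaks <- c(peaks, p)
  }
  peaks <- sort(peaks)
  if (length(peaks) < 2) abort("fewer than 2 troughs: unsegmentable record")
  first_tr <- which.min(sm[seq_len(peaks[1])])
  joints <- vapply(seq_len(length(peaks) - 1), function(i) {
    span <- peaks[i]:peaks[i + 1]
    span[which.min(sm[span])]
  }, 0L)
  troughs <- c(first_tr, joints)
  out <- tibble::tibble(start = troughs[-length(troughs)] - 1L,
                        end = troughs[-1] - 1L)
  attr(out, "troughs") <- troughs - 1L
  out
}

#' Resample one beat to the model's fixed cycle length
#'
#' Linearly interpolates a trough-to-trough segment onto `length_out` (235 by
#' default) evenly spaced points and min-max normalises it to `[0, 1]`, so
#' beats from devices with different sampling rates and gains share one input
#' grid.
#'
#' @param segment numeric series (length >= 4, non-constant).
#' @param length_out output length (default 235).
#' @return object of class `pwc_beat`: numeric vector of length `length_out`.
#' @export
resample_beat <- function(segment, length_out = 235) {
  n <- length(segment)
  if (n < 4) abort("segment too short to resample")
  rng <- range(segment)
  if (diff(rng) <= 0) abort("constant segment: normalization undefined")
  y <- approx(seq(0, 1, length.out = n), segment,
              xout = seq(0, 1, length.out = length_out))$y
  y <- (y - min(y)) / (max(y) - min(y))
  structure(y, class = "pwc_beat")
}

#' Group consecutive beats into model input windows
#'
#' Stacks non-overlapping runs of `n_cycles` consecutive beats from one record
#' into matrices of `n_cycles` rows by 235 columns; a trailing remainder
#' shorter than `n_cycles` is dropped. `overlap` rows of each window may be
#' shared with the previous one.
#'
#' @param beats list of length-235 beats (e.g. from [resample_beat()]).
#' @param label class label in `{0, 1}` attached to every window.
#' @param n_cycles beats per window (default 5).
#' @param overlap beats shared between consecutive windows (default 0).
#' @return list of `beat_window` objects (possibly empty); each has fields
#'   `beats` (n_cycles x 235 matrix), `label`, `n_cycles`.
#' @export
window_beats <- function(beats, label, n_cycles = 5, overlap = 0) {
  if (n_cycles < 1) abort("n_cycles must be >= 1")
  if (overlap < 0 || overlap >= n_cycles) abort("overlap must be in [0, n_cycles)")
  k <- length(beats)
  if (k < n_cycles) return(list())
  step <- n_cycles - overlap
  starts <- seq(1, k - n_cycles + 1, by = step)
  lapply(starts, function(s) {
    m <- do.call(rbind, lapply(beats[s:(s + n_cycles - 1)], as.numeric))
    structure(list(beats = m, label = as.integer(label), n_cycles = n_cycles),
              class = "beat_window")
  })
}

#' Full preprocessing pipeline over a set of records
#'
#' For each record: EMD denoising in `band`, the Pearson retention gate at
#' `threshold`, trough segmentation, per-beat resampling to length 235 and
#' grouping into `n_cycles`-beat windows. Records that fail the gate or
#' cannot be segmented are dropped and logged.
#'
#' @param records list of `signal_record`s.
#' @param band IMF retention band in Hz (see [denoise()]).
#' @param threshold Pearson retention threshold.
#' @param n_cycles beats per window.
#' @param overlap beats shared between windows.
#' @return list with `windows` (list of `beat_window`), `provenance` (tibble:
#'   record_id, label, kept, pearson, n_beats, n_windows, reason).
#' @export
preprocess_records <- function(records, band = c(0.4, 20), threshold = 0.93,
                               n_cycles = 5, overlap = 0) {
  rows <- vector("list", length(records))
  windows <- list()
  for (i in seq_along(records)) {
    rec <- records[[i]]
    res <- tryCatch({
      den <- denoise(rec, band = band)
      keep <- retention_filter(rec$samples, den, threshold)
      if (!keep) {
        list(kept = FALSE, pearson = attr(keep, "pearson"),
             n_beats = 0L, wins = list(), reason = "pearson_gate")
      } else {
        seg <- segment_beats(den, rec$fs)
        beats <- lapply(seq_len(nrow(seg)), function(j)
          resample_beat(den[(seg$start[j] + 1):(seg$end[j])]))
        wins <- window_beats(beats, rec$label, n_cycles, overlap)
        list(kept = TRUE, pearson = attr(keep, "pearson"),
             n_beats = length(beats), wins = wins, reason = NA_character_)
      }
    }, error = function(e) list(kept = FALSE, pearson = NA_real_, n_beats = 0L,
                                wins = list(), reason = conditionMessage(e)))
    rows[[i]] <- tibble::tibble(
      record_id = rec$record_id, label = rec$label, kept = res$kept,
      pearson = res$pearson, n_beats = res$n_beats,
      n_windows = length(res$wins), reason = res$reason)
    windows <- c(windows, res$wins)
  }
  list(windows = windows, provenance = dplyr::bind_rows(rows))
}

#' Stack beat windows into an array for the model
#'
#' @param windows list of `beat_window`s with equal `n_cycles`.
#' @return list with `x` (array n_windows x n_cycles x 235) and `y`
#'   (integer labels).
#' @export
windows_to_array <- function(windows) {
  if (length(windows) == 0) abort("no windows")
  n <- length(windows)
  nc <- windows[[1]]$n_cycles
  len <- ncol(windows[[1]]$beats)
  x <- array(0, c(n, nc, len))
  for (i in seq_len(n)) x[i, , ] <- windows[[i]]$beats
  list(x = x, y = vapply(windows, `[[`, 1L, "label"))
}
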