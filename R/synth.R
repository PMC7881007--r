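#' Beat morphology parameters
#'
#' A single pulse beat is modelled as the sum of three Gaussian bumps on the
#' unit interval: the systolic upstroke, the reflected wave and the dicrotic
#' wave. Centres and widths are fractions of the beat duration; amplitudes are
#' dimensionless (each noise-free beat is later min-max normalised to
#' \eqn{[0, 1]}).
#'
#' @param systolic_amplitude,reflected_amplitude,dicrotic_amplitude bump
#'   heights; `systolic_amplitude` must be positive and at least
#'   `reflected_amplitude`.
#' @param systolic_center,reflected_center,dicrotic_center bump centres in
#'   (0, 1), strictly increasing in that order.
#' @param systolic_width,reflected_width,dicrotic_width bump standard
#'   deviations as fractions of the beat, all positive.
#' @return an object of class `beat_morphology`.
#' @export
beat_morphology <- function(systolic_amplitude = 1,
                            systolic_center = 0.18,
                            systolic_width = 0.045,
                            reflected_amplitude = 0.35,
                            reflected_center = 0.42,
                            reflected_width = 0.08,
                            dicrotic_amplitude = 0.25,
                            dicrotic_center = 0.62,
                            dicrotic_width = 0.05) {
  m <- list(
    systolic_amplitude = systolic_amplitude,
    systolic_center = systolic_center,
    systolic_width = systolic_width,
    reflected_amplitude = reflected_amplitude,
    reflected_center = reflected_center,
    reflected_width = reflected_width,
    dicrotic_amplitude = dicrotic_amplitude,
    dicrotic_center = dicrotic_center,
    dicrotic_width = dicrotic_width
  )
  widths <- c(m$systolic_width, m$reflected_width, m$dicrotic_width)
  if (any(widths <= 0)) abort("all bump widths must be positive")
  if (m$systolic_amplitude <= 0) abort("systolic amplitude must be positive")
  if (m$reflected_amplitude < 0 || m$dicrotic_amplitude < 0)
    abort("reflected and dicrotic amplitudes must be non-negative")
  if (m$systolic_amplitude < m$reflected_amplitude)
    abort("systolic amplitude must be >= reflected amplitude")
  ctr <- c(m$systolic_center, m$reflected_center, m$dicrotic_center)
  if (any(ctr <= 0) || any(ctr >= 1) || any(diff(ctr) <= 0))
    abort("centres must lie in (0,1) and increase: systolic < reflected < dicrotic")
  structure(m, class = "beat_morphology")
}

#' Noise specification for synthetic records
#'
#' Additive interference emulating what contaminates clinically collected
#' pulse waves: respiration baseline wander (normal adult breathing sits
#' around 0.2-0.3 Hz), mains powerline pickup (50 or 60 Hz), wide-band
#' instrument noise above 90 Hz, and white sensor noise. Amplitudes are in
#' the same dimensionless units as the normalised beats; the instrument
#' component is scaled to the requested RMS.
#'
#' @param respiration_hz breathing rate in Hz, in `[0.2, 0.3]`.
#' @param respiration_amplitude,powerline_amplitude,instrument_amplitude,white_sigma
#'   component amplitudes (>= 0); zero disables a component.
#' @param powerline_hz mains frequency, 50 or 60.
#' @param instrument_band_low_hz lower edge of the instrument band (>= 90 Hz).
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(respiration_hz = 0.25, respiration_amplitude = 0,
                       powerline_hz = 50, powerline_amplitude = 0,
                       instrument_band_low_hz = 90, instrument_amplitude = 0,
                       white_sigma = 0) {
  if (respiration_hz < 0.2 || respiration_hz > 0.3)
    abort("respiration_hz must lie in [0.2, 0.3]")
  if (!powerline_hz %in% c(50, 60)) abort("powerline_hz must be 50 or 60")
  if (instrument_band_low_hz < 90)
    abort("instrument_band_low_hz must be >= 90")
  amps <- c(respiration_amplitude, powerline_amplitude, instrument_amplitude,
            white_sigma)
  if (any(amps < 0)) abort("noise amplitudes must be non-negative")
  structure(list(
    respiration_hz = respiration_hz,
    respiration_amplitude = respiration_amplitude,
    powerline_hz = powerline_hz,
    powerline_amplitude = powerline_amplitude,
    instrument_band_low_hz = instrument_band_low_hz,
    instrument_amplitude = instrument_amplitude,
    white_sigma = white_sigma
  ), class = "noise_spec")
}

#' Preset noise conditions
#'
#' `"clean"` disables all interference; `"ppg"` mimics an optical finger
#' sensor (pronounced respiration wander, mains pickup, wide-band instrument
#' noise); `"cnbp"` mimics a wrist pressure sensor (milder interference).
#'
#' @param preset one of `"clean"`, `"ppg"`, `"cnbp"`.
#' @return a [noise_spec()].
#' @export
noise_preset <- function(preset = c("clean", "ppg", "cnbp")) {
  preset <- match.arg(preset)
  switch(preset,
    clean = noise_spec(),
    ppg = noise_spec(respiration_hz = 0.25, respiration_amplitude = 0.30,
                     powerline_hz = 50, powerline_amplitude = 0.10,
                     instrument_band_low_hz = 90, instrument_amplitude = 0.04,
                     white_sigma = 0.03),
    cnbp = noise_spec(respiration_hz = 0.25, respiration_amplitude = 0.08,
                      powerline_hz = 50, powerline_amplitude = 0.04,
                      instrument_band_low_hz = 90, instrument_amplitude = 0.015,
                      white_sigma = 0.015)
  )
}

#' Generate one synthetic beat
#'
#' Evaluates the three-Gaussian beat model on `n_samples` points covering one
#' trough-to-trough cycle (the grid spans `[0, 1)` so that concatenated beats
#' tile seamlessly). With `normalize = TRUE` the beat is shifted and scaled to
#' min 0, max 1.
#'
#' @param morph a [beat_morphology()].
#' @param n_samples number of samples (>= 8).
#' @param normalize min-max normalise the beat to `[0, 1]` (default `TRUE`).
#' @return numeric vector of length `n_samples`.
#' @export
make_beat <- function(morph, n_samples, normalize = TRUE) {
  if (!inherits(morph, "beat_morphology")) morph <- do.call(beat_morphology, morph)
  if (n_samples < 8) abort("n_samples must be >= 8")
  t <- (seq_len(n_samples) - 1) / n_samples
  bump <- function(a, c0, w) a * exp(-0.5 * ((t - c0) / w)^2)
  y <- bump(morph$systolic_amplitude, morph$systolic_center, morph$systolic_width) +
    bump(morph$reflected_amplitude, morph$reflected_center, morph$reflected_width) +
    bump(morph$dicrotic_amplitude, morph$dicrotic_center, morph$dicrotic_width)
  if (normalize) {
    rng <- range(y)
    if (diff(rng) <= 0) abort("degenerate beat: constant series")
    y <- (y - rng[1]) / diff(rng)
  }
  y
}

# class-conditional morphology distributions: the abnormal class has an
# elevated reflected wave and an attenuated dicrotic wave (a standard
# hypertension-related contrast). Sampled once per record.
sample_morphology <- function(class_id) {
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  if (class_id == 0) {
    refl <- clamp(rnorm(1, 0.35, 0.04), 0.15, 0.55)
    dicr <- clamp(rnorm(1, 0.25, 0.03), 0.10, 0.40)
    rc <- clamp(rnorm(1, 0.42, 0.015), 0.35, 0.50)
  } else {
    refl <- clamp(rnorm(1, 0.62, 0.04), 0.45, 0.85)
    dicr <- clamp(rnorm(1, 0.10, 0.025), 0.02, 0.20)
    rc <- clamp(rnorm(1, 0.46, 0.015), 0.38, 0.54)
  }
  beat_morphology(
    systolic_amplitude = 1,
    systolic_center = clamp(rnorm(1, 0.18, 0.01), 0.12, 0.25),
    systolic_width = clamp(rnorm(1, 0.045, 0.004), 0.03, 0.06),
    reflected_amplitude = refl,
    reflected_center = rc,
    reflected_width = clamp(rnorm(1, 0.08, 0.006), 0.06, 0.11),
    dicrotic_amplitude = dicr,
    dicrotic_center = clamp(rnorm(1, 0.62, 0.015), 0.55, 0.70),
    dicrotic_width = clamp(rnorm(1, 0.05, 0.004), 0.035, 0.07)
  )
}

# per-class beat-to-beat variability defaults (timing jitter and reflected-
# wave wobble share this fraction); the abnormal class is the more irregular.
default_jitter <- function(class_id) if (class_id == 0) 0.03 else 0.08

band_noise <- function(n, fs, f_lo, rms) {
  if (rms <= 0) return(numeric(n))
  f_hi <- fs / 2
  if (f_lo >= f_hi) return(numeric(n))
  w <- rnorm(n)
  sp <- fft(w)
  freqs <- (seq_len(n) - 1) * fs / n
  keep <- (freqs >= f_lo & freqs <= f_hi) | (freqs >= fs - f_hi & freqs <= fs - f_lo)
  sp[!keep] <- 0
  x <- Re(fft(sp, inverse = TRUE)) / n
  s <- sd(x)
  if (s == 0) return(numeric(n))
  x / s * rms
}

#' Generate one synthetic pulse wave record
#'
#' Concatenates `n_beats` trough-to-trough beats whose durations are
#' `(60 / heart_rate_bpm) * (1 + u)` seconds with `u` uniform in
#' `+/- jitter_frac`, using a class-specific morphology drawn once per record
#' (class 1 has an elevated reflected wave and an attenuated dicrotic wave).
#' The same jitter fraction also drives beat-to-beat wobble of the reflected
#' wave, so rhythm irregularity carries class signal too. All
#' [noise_spec()] components are then added. Fully reproducible from `seed`.
#'
#' @param class_id 0 (normal-like) or 1 (abnormal-like).
#' @param n_beats number of beats (>= 2).
#' @param fs sampling rate in Hz.
#' @param heart_rate_bpm mean heart rate in beats per minute.
#' @param jitter_frac beat-duration jitter fraction in `[0, 0.2]`; `NULL`
#'   selects the class default (0.03 normal, 0.08 abnormal).
#' @param noise a [noise_spec()]; default clean.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param record_id,subject_id identifiers (defaults derived from class/seed).
#' @return an object of class `signal_record` with fields `samples`, `fs`,
#'   `label`, `record_id`, `subject_id`, plus generator ground truth
#'   `beat_boundaries` (0-based sample index of each trough-to-trough
#'   boundary) and the drawn `morphology`.
#' @export
make_record <- function(class_id, n_beats, fs = 200, heart_rate_bpm = 70,
                        jitter_frac = NULL, noise = noise_preset("clean"),
                        seed = NULL, record_id = NULL, subject_id = NULL) {
  if (!class_id %in% c(0, 1)) abort("class_id must be 0 or 1")
  if (n_beats < 2) abort("n_beats must be >= 2")
  if (fs <= 0 || heart_rate_bpm <= 0) abort("fs and heart_rate_bpm must be positive")
  if (is.null(jitter_frac)) jitter_frac <- default_jitter(class_id)
  if (jitter_frac < 0 || jitter_frac > 0.2) abort("jitter_frac must lie in [0, 0.2]")
  if (noise$powerline_amplitude > 0 && fs < 2 * noise$powerline_hz)
    abort("fs too low to represent the powerline component (fs < 2*powerline_hz)")

  with_seed_if(seed, {
    morph <- sample_morphology(class_id)
    u <- if (jitter_frac > 0) runif(n_beats, -jitter_frac, jitter_frac) else numeric(n_beats)
    wob <- if (jitter_frac > 0) runif(n_beats, -jitter_frac, jitter_frac) else numeric(n_beats)
    n_per_beat <- round(fs * (60 / heart_rate_bpm) * (1 + u))
    n_per_beat <- pmax(n_per_beat, 8L)
    beats <- lapply(seq_len(n_beats), function(i) {
      m <- morph
      m$reflected_amplitude <- min(m$reflected_amplitude * (1 + wob[i]),
                                   m$systolic_amplitude)
      make_beat(m, n_per_beat[i])
    })
    x <- unlist(beats, use.names = FALSE)
    n <- length(x)
    tt <- (seq_len(n) - 1) / fs
    if (noise$respiration_amplitude > 0)
      x <- x + noise$respiration_amplitude *
        sin(2 * pi * noise$respiration_hz * tt + runif(1, 0, 2 * pi))
    if (noise$powerline_amplitude > 0)
      x <- x + noise$powerline_amplitude *
        sin(2 * pi * noise$powerline_hz * tt + runif(1, 0, 2 * pi))
    if (noise$instrument_amplitude > 0)
      x <- x + band_noise(n, fs, noise$instrument_band_low_hz,
                          noise$instrument_amplitude)
    if (noise$white_sigma > 0) x <- x + rnorm(n, sd = noise$white_sigma)

    structure(list(
      samples = x,
      fs = fs,
      label = as.integer(class_id),
      record_id = record_id %||% sprintf("rec_c%d_s%s", class_id,
                                         seed %||% "live"),
      subject_id = subject_id %||% sprintf("sub_%s", seed %||% "live"),
      beat_boundaries = cumsum(c(0L, n_per_beat)),
      morphology = morph,
      heart_rate_bpm = heart_rate_bpm,
      jitter_frac = jitter_frac
    ), class = "signal_record")
  })
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record %s> %d samples @ %g Hz, label %d, subject %s\n",
              x$record_id, length(x$samples), x$fs, x$label, x$subject_id))
  invisible(x)
}

#' Generate a balanced labelled dataset of synthetic records
#'
#' Draws `n_records_per_class` records per class with per-record heart rates
#' uniform in `heart_rate_range`. Per-record seeds are derived
#' deterministically from `seed`, so the dataset (and its manifest) is fully
#' reproducible. Optionally writes one `t,amplitude` CSV per record plus a
#' `manifest.csv` to `dir`.
#'
#' @param n_records_per_class records per class (>= 1).
#' @param n_beats beats per record.
#' @param fs sampling rate in Hz.
#' @param heart_rate_range range (bpm) from which each record's rate is drawn.
#' @param jitter_frac beat jitter; `NULL` = class defaults.
#' @param noise a [noise_spec()].
#' @param seed master seed.
#' @param dir optional output directory for the on-disk container format.
#' @return list with `records` (list of [make_record()] results) and
#'   `manifest` (a tibble: record_id, subject_id, label, fs, n_beats,
#'   heart_rate_bpm, jitter_frac, seed).
#' @export
make_dataset <- function(n_records_per_class, n_beats = 60, fs = 200,
                         heart_rate_range = c(60, 90), jitter_frac = NULL,
                         noise = noise_preset("clean"), seed = 1, dir = NULL) {
  if (n_records_per_class < 1) abort("n_records_per_class must be >= 1")
  classes <- rep(c(0L, 1L), each = n_records_per_class)
  n_total <- length(classes)
  rec_seeds <- (as.integer(seed) %% 100000L) * 10000L + seq_len(n_total)
  hrs <- with_seed_if(seed,
                      runif(n_total, heart_rate_range[1], heart_rate_range[2]))
  records <- lapply(seq_len(n_total), function(i) {
    make_record(classes[i], n_beats = n_beats, fs = fs,
                heart_rate_bpm = hrs[i], jitter_frac = jitter_frac,
                noise = noise, seed = rec_seeds[i],
                record_id = sprintf("rec%04d", i),
                subject_id = sprintf("sub%04d", i))
  })
  manifest <- tibble::tibble(
    record_id = vapply(records, `[[`, "", "record_id"),
    subject_id = vapply(records, `[[`, "", "subject_id"),
    label = vapply(records, `[[`, 1L, "label"),
    fs = fs,
    n_beats = n_beats,
    heart_rate_bpm = round(hrs, 6),
    jitter_frac = vapply(records, `[[`, 1, "jitter_frac"),
    seed = rec_seeds
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (r in records) write_record(r, file.path(dir, paste0(r$record_id, ".csv")))
    utils::write.csv(as.data.frame(manifest),
                     file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(records = records, manifest = manifest)
}

#' Write / read a record as CSV
#'
#' The on-disk container is one CSV per record with columns `t` (seconds) and
#' `amplitude`; label and identifiers travel in the dataset manifest or can be
#' passed to `read_record()` directly.
#'
#' @param record a `signal_record`.
#' @param path CSV file path.
#' @export
write_record <- function(record, path) {
  df <- data.frame(t = (seq_along(record$samples) - 1) / record$fs,
                   amplitude = record$samples)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_record
#' @param fs,label,record_id,subject_id metadata to attach on read (fs is
#'   inferred from the `t` column when `NULL`).
#' @export
read_record <- function(path, fs = NULL, label = NA_integer_,
                        record_id = basename(path), subject_id = NA_character_) {
  df <- utils::read.csv(path)
  if (is.null(fs)) fs <- 1 / stats::median(diff(df$t))
  structure(list(samples = df$amplitude, fs = fs, label = label,
                 record_id = record_id, subject_id = subject_id),
            class = "signal_record")
}

#' @export
autoplot.signal_record <- function(object, seconds = NULL, ...) {
  n <- length(object$samples)
  if (!is.null(seconds)) n <- min(n, round(seconds * object$fs))
  df <- data.frame(t = (seq_len(n) - 1) / object$fs,
                   amplitude = object$samples[seq_len(n)])
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "amplitude (a.u.)",
                  title = sprintf("%s (label %s)", object$record_id, object$label))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
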