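test_that("pearson_cor matches the raw-sum formula", {
  set.seed(2)
  x <- rnorm(50)
  expect_equal(pearson_cor(x, x), 1.0)
  expect_equal(pearson_cor(x, -x), -1.0)

  # hand-summed evaluation on a small example
  a <- c(1, 2, 3, 4); b <- c(2, 4, 5, 9)
  n <- 4
  num <- sum(a * b) - sum(a) * sum(b) / n
  den <- sqrt((sum(a^2) - sum(a)^2 / n) * (sum(b^2) - sum(b)^2 / n))
  expect_equal(pearson_cor(a, b), num / den)
  expect_equal(pearson_cor(a, b), stats::cor(a, b))

  expect_error(pearson_cor(a, b[1:3]), "equal length")
  expect_error(pearson_cor(rep(1, 5), 1:5), "constant")
})

test_that("the retention gate is strict at the 0.93 threshold", {
  n <- 1000
  x <- sin(seq(0, 20, length.out = n))
  # construct a companion series with an exactly known correlation by
  # mixing in an orthogonalised perturbation
  make_with_r <- function(r) {
    set.seed(1)
    z <- rnorm(n)
    z <- residuals(lm(z ~ x))
    z <- z / sd(z)
    xs <- (x - mean(x)) / sd(x)
    r * xs + sqrt(1 - r^2) * z
  }
  y99 <- make_with_r(0.99)
  expect_true(retention_filter(x, y99))
  y93 <- make_with_r(0.93)
  expect_equal(attr(retention_filter(x, y93), "pearson"), 0.93, tolerance = 1e-10)
  # the gate is strictly "greater than": at the exact threshold it discards
  r_exact <- pearson_cor(x, y93)
  expect_false(retention_filter(x, y93, threshold = r_exact))
  expect_true(retention_filter(x, y93, threshold = r_exact - 1e-12))
  expect_false(retention_filter(x, make_with_r(0.50)))
})

test_that("denoising preserves clean signals and removes the noise bands", {
  clean <- make_record(0, 60, fs = 200, heart_rate_bpm = 72, jitter_frac = 0,
                       noise = noise_preset("clean"), seed = 5)
  d <- denoise(clean)
  expect_gte(pearson_cor(clean$samples, d), 0.999)

  # powerline: >= 20 dB suppression at 50 Hz
  noisy <- make_record(0, 30, fs = 200, heart_rate_bpm = 70, jitter_frac = 0,
                       noise = noise_spec(powerline_amplitude = 0.2), seed = 11)
  dn <- denoise(noisy)
  band_power <- function(x, fs, lo, hi) {
    n <- length(x)
    p <- (Mod(fft(x - mean(x)))^2)[seq_len(n %/% 2)]
    f <- (seq_len(n %/% 2) - 1) * fs / n
    sum(p[f >= lo & f <= hi])
  }
  supp <- 10 * log10(band_power(noisy$samples, 200, 49, 51) /
                     band_power(dn, 200, 49, 51))
  expect_gte(supp, 20)

  # respiration drift: 2-s moving-average variability is reduced
  drifty <- make_record(0, 30, fs = 200, heart_rate_bpm = 70,
                        noise = noise_spec(respiration_hz = 0.25,
                                           respiration_amplitude = 0.3),
                        seed = 13)
  dd <- denoise(drifty)
  slow <- function(x) sd(stats::filter(x, rep(1 / 400, 400), sides = 2),
                         na.rm = TRUE)
  expect_lt(slow(dd), slow(drifty$samples))

  expect_error(denoise(clean$samples), "fs")
  expect_error(denoise(rep(0.5, 100), fs = 200), "unusable|no IMFs")
})

test_that("segmentation recovers generator beat boundaries on noise-free records", {
  for (s in c(1, 2)) for (cl in 0:1) {
    k <- 12
    hr <- c(64, 82)[s]
    r <- make_record(cl, k, fs = 200, heart_rate_bpm = hr,
                     noise = noise_preset("clean"), seed = 50 + s * 2 + cl)
    seg <- segment_beats(r$samples, 200)
    expect_equal(nrow(seg), k - 1)
    err <- vapply(attr(seg, "troughs"),
                  function(t) min(abs(t - r$beat_boundaries)), 0)
    expect_lte(max(err), 3)
    # intervals within the jitter envelope of the nominal beat
    nominal <- 200 * 60 / hr
    lens <- seg$end - seg$start
    expect_true(all(abs(lens - nominal) <= 0.1 * nominal + 3))
  }
  expect_error(segment_beats(seq_len(400) / 10, 200), "unsegmentable")
})

test_that("resample_beat maps any segment onto 235 normalised points", {
  ramp <- seq(2, 7, length.out = 101)
  rb <- resample_beat(ramp)
  expect_length(rb, 235)
  expect_equal(as.numeric(rb), seq(0, 1, length.out = 235), tolerance = 1e-12)

  # identity grid up to normalisation
  set.seed(3)
  x <- cumsum(rnorm(235))
  rb2 <- resample_beat(x)
  expect_equal(as.numeric(rb2), (x - min(x)) / (max(x) - min(x)),
               tolerance = 1e-12)

  # node-coincident upsampling round trip: a 469-point linear upsample puts
  # every original sample back on the 235-point grid exactly
  beat <- make_beat(beat_morphology(), 235)
  up <- approx(seq(0, 1, length.out = 235), beat,
               xout = seq(0, 1, length.out = 469))$y
  back <- resample_beat(up)
  expect_lt(max(abs(as.numeric(back) - beat)), 1e-6)
  # sample-duplication upsampling recovers the beat to interpolation error
  dup <- rep(beat, each = 2)
  expect_lt(max(abs(as.numeric(resample_beat(dup)) - beat)), 0.02)

  expect_error(resample_beat(c(1, 2, 3)), "short")
  expect_error(resample_beat(rep(2, 50)), "constant")
})

test_that("window grouping follows the integer-division contract", {
  beats <- replicate(12, resample_beat(make_beat(beat_morphology(), 200)),
                     simplify = FALSE)
  expect_length(window_beats(beats, 1, n_cycles = 5), 2)
  expect_length(window_beats(beats[1:5], 1, n_cycles = 5), 1)
  expect_length(window_beats(beats[1:4], 1, n_cycles = 5), 0)
  w <- window_beats(beats, 0, n_cycles = 5)[[1]]
  expect_equal(dim(w$beats), c(5, 235))
  expect_equal(w$label, 0L)
  # overlap produces the expected stride
  expect_length(window_beats(beats, 1, n_cycles = 5, overlap = 2), 3)
  # windows preserve beat order
  expect_equal(w$beats[3, ], as.numeric(beats[[3]]))
})

test_that("the full preprocessing pipeline keeps clean records and logs provenance", {
  ds <- make_dataset(3, n_beats = 12, seed = 9, noise = noise_preset("clean"))
  pp <- preprocess_records(ds$records)
  expect_true(all(pp$provenance$kept))
  expect_true(all(pp$provenance$pearson > 0.93))
  expect_gt(length(pp$windows), 0)
  da <- windows_to_array(pp$windows)
  expect_equal(dim(da$x)[2:3], c(5, 235))
  expect_equal(length(da$y), dim(da$x)[1])
})
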