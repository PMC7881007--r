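#' Locate interior local extrema
#'
#' Strict sign-change detection on first differences, with plateaus collapsed
#' to their midpoint. Endpoints are never reported as extrema (they enter the
#' envelopes through [extend_endpoints()] instead).
#'
#' @param x numeric series.
#' @return list with integer vectors `maxima` and `minima` (1-based indices).
#' @export
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(maxima = integer(0), minima = integer(0)))
  # collapse exact plateaus so flat tops count once, at their midpoint
  r <- rle(x)
  k <- length(r$values)
  if (k < 3) return(list(maxima = integer(0), minima = integer(0)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  mid <- (starts + ends) %/% 2
  v <- r$values
  i <- 2:(k - 1)
  is_max <- v[i] > v[i - 1] & v[i] > v[i + 1]
  is_min <- v[i] < v[i - 1] & v[i] < v[i + 1]
  list(maxima = mid[i[is_max]], minima = mid[i[is_min]])
}

#' Add series endpoints as spline knots
#'
#' Cubic-spline envelopes fitted through extrema alone diverge at the edges of
#' the record (the spline is unconstrained beyond the first and last knots),
#' which distorts the start and end of every filtered signal. The remedy used
#' here anchors the envelope by inserting the first and last samples of the
#' series as additional knots. Indices are 0-based to match the package's
#' interval convention.
#'
#' @param extrema_idx 0-based indices of the interior extrema (increasing).
#' @param extrema_val values at those extrema.
#' @param n series length.
#' @param first_val,last_val series values at samples `0` and `n - 1`.
#' @return list with `idx` (0-based knot indices) and `val`; endpoints are not
#'   duplicated when an extremum already sits there.
#' @export
extend_endpoints <- function(extrema_idx, extrema_val, n, first_val, last_val) {
  if (length(extrema_idx) == 0) abort("no interior extrema: monotone segment")
  if (length(extrema_idx) != length(extrema_val))
    abort("extrema_idx and extrema_val lengths differ")
  idx <- extrema_idx
  val <- extrema_val
  if (idx[1] != 0) { idx <- c(0, idx); val <- c(first_val, val) }
  if (idx[length(idx)] != n - 1) { idx <- c(idx, n - 1); val <- c(val, last_val) }
  list(idx = idx, val = val)
}

# natural cubic spline envelope through (idx, val), evaluated on 1..n (1-based)
envelope_spline <- function(idx0, val, n) {
  if (length(idx0) == 1) return(rep(val, n))
  if (length(idx0) < 4) {
    # too few knots for a cubic: linear interpolation keeps the envelope tame
    return(approx(idx0, val, xout = 0:(n - 1), rule = 2)$y)
  }
  f <- splinefun(idx0, val, method = "natural")
  f(0:(n - 1))
}

count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

# one sifting pass: subtract the mean of the endpoint-anchored envelopes.
# On top of the endpoint anchoring, the outermost extrema are mirrored about
# the record edges so the spline has support beyond both ends; this keeps the
# boundary transient from leaking several beats into the record.
sift_once <- function(h) {
  n <- length(h)
  ex <- find_extrema(h)
  if (length(ex$maxima) < 1 || length(ex$minima) < 1) return(NULL)
  # endpoint anchoring with the value clamped against the nearest extremum
  # (an endpoint sitting at a trough must not drag the *upper* envelope
  # down, and vice versa), plus one mirrored extremum beyond each edge
  knots <- function(ex_idx, ex_val, clamp) {
    k <- length(ex_idx)
    first_v <- clamp(h[1], ex_val[1])
    last_v <- clamp(h[n], ex_val[k])
    kn <- extend_endpoints(ex_idx - 1, ex_val, n, first_v, last_v)
    idx <- kn$idx; val <- kn$val
    if (ex_idx[1] > 1) { idx <- c(-(ex_idx[1] - 1), idx); val <- c(ex_val[1], val) }
    if (ex_idx[k] < n) {
      idx <- c(idx, 2 * (n - 1) - (ex_idx[k] - 1))
      val <- c(val, ex_val[k])
    }
    keep <- !duplicated(idx)
    list(idx = idx[keep], val = val[keep])
  }
  up <- knots(ex$maxima, h[ex$maxima], max)
  lo <- knots(ex$minima, h[ex$minima], min)
  upper <- envelope_spline(up$idx, up$val, n)
  lower <- envelope_spline(lo$idx, lo$val, n)
  h - (upper + lower) / 2
}

#' Empirical mode decomposition
#'
#' Decomposes a series into intrinsic mode functions (IMFs) by standard
#' sifting: the mean of the upper and lower cubic-spline envelopes (natural
#' splines through the maxima/minima, anchored at the series endpoints via
#' [extend_endpoints()]) is subtracted until the Cauchy criterion
#' \eqn{\sum (h_{k-1} - h_k)^2 / \sum h_{k-1}^2 \le} `sd_thresh` holds or
#' `max_sifts` passes have run. Extraction stops when the residue has fewer
#' than two interior maxima or minima, or after `max_imfs` IMFs. The residue
#' is defined as the input minus the IMF sum, so the decomposition is
#' additive-exact by construction.
#'
#' @param x numeric series (length >= 16 with at least 2 maxima and 2 minima
#'   for a non-trivial decomposition; monotone/constant inputs yield zero IMFs
#'   and `residue = x`).
#' @param max_imfs maximum number of IMFs (default 10).
#' @param sd_thresh Cauchy sifting-stop threshold (default 0.2).
#' @param max_sifts maximum sifting passes per IMF (default 10).
#' @return object of class `imf_set`: list with `imfs` (list of series) and
#'   `residue`.
#' @export
emd <- function(x, max_imfs = 10, sd_thresh = 0.2, max_sifts = 10) {
  n <- length(x)
  imfs <- list()
  residue <- x
  while (length(imfs) < max_imfs) {
    ex <- find_extrema(residue)
    if (length(ex$maxima) < 2 || length(ex$minima) < 2) break
    h <- residue
    for (k in seq_len(max_sifts)) {
      h_new <- sift_once(h)
      if (is.null(h_new)) break
      num <- sum((h - h_new)^2)
      den <- sum(h^2)
      h <- h_new
      if (den == 0 || num / den <= sd_thresh) break
    }
    imfs[[length(imfs) + 1]] <- h
    residue <- residue - h
  }
  # exact additivity: define the residue as what is left of the input
  residue <- x - Reduce(`+`, imfs, numeric(n))
  structure(list(imfs = imfs, residue = residue), class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs + residue (length %d)\n",
              length(x$imfs), length(x$residue)))
  invisible(x)
}

#' Summarise an IMF set
#'
#' @param x an `imf_set`.
#' @param fs sampling rate in Hz (for dominant frequencies).
#' @return tibble with one row per IMF: index, dominant frequency, RMS,
#'   numbers of extrema and zero crossings.
#' @export
imf_summary <- function(x, fs) {
  purrr::map_dfr(seq_along(x$imfs), function(i) {
    im <- x$imfs[[i]]
    ex <- find_extrema(im)
    tibble::tibble(
      imf = i,
      dominant_hz = dominant_freq(im, fs),
      rms = sqrt(mean(im^2)),
      n_extrema = length(ex$maxima) + length(ex$minima),
      n_zero_crossings = count_zero_crossings(im)
    )
  })
}
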