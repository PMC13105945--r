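#' Define the EMG frequency-band scheme
#'
#' Builds the ordered set of equal-width frequency bands used for the
#' spectral decomposition. Bands are laid on the spectral bin grid with a
#' half-open convention: a band starting at `low` owns the bins in
#' `[low, low + width)`, i.e. `width / bin_width` bins (39 for the default
#' 19.5 Hz bands on a 0.5 Hz grid). Consecutive bands start `width +
#' bin_width` apart, reproducing the conventional printed edges
#' F1 = [10, 29.5], F2 = [30, 49.5], ..., F10 = [205, 224.5]. A band whose
#' span would intersect an exclusion zone (by default the 50-65 Hz interval
#' contaminated by the 60 Hz notch) is pushed to the zone's upper edge.
#'
#' @param low Lower edge of the first band in Hz.
#' @param width Band width in Hz; must be a multiple of `bin_width`.
#' @param count Number of bands.
#' @param bin_width Spectral bin width in Hz.
#' @param exclusions List of `c(low, high)` zones no band may intersect;
#'   zone edges must sit on the bin grid.
#' @param max_freq Optional frequency ceiling (e.g. Nyquist); exceeding it
#'   is an error.
#' @return An object of class `acfc_band_scheme`: data frame `bands` with
#'   columns `label`, `low`, `high` (printed inclusive edges) plus fields
#'   `bin_width` and `exclusions`.
#' @export
#' @examples
#' sch <- make_band_scheme()
#' sch$bands
make_band_scheme <- function(low = 10, width = 19.5, count = 10,
                             bin_width = 0.5,
                             exclusions = list(c(50, 65)),
                             max_freq = NULL) {
  nb <- width / bin_width
  if (abs(nb - round(nb)) > 1e-9) {
    stop("make_band_scheme: width must be a multiple of bin_width")
  }
  for (z in exclusions) {
    if (any(abs(z / bin_width - round(z / bin_width)) > 1e-9)) {
      stop("make_band_scheme: exclusion zones must align to the bin grid")
    }
  }
  starts <- numeric(count)
  s <- low
  for (i in seq_len(count)) {
    repeat {
      hit <- FALSE
      for (z in exclusions) {
        # half-open band [s, s + width) vs half-open zone [z1, z2)
        if (s < z[2] && (s + width) > z[1]) {
          s <- z[2]
          hit <- TRUE
        }
      }
      if (!hit) break
    }
    starts[i] <- s
    s <- s + width + bin_width
  }
  if (!is.null(max_freq) && (starts[count] + width) > max_freq) {
    stop("make_band_scheme: bands exceed the frequency ceiling (Nyquist)")
  }
  bands <- data.frame(label = paste0("F", seq_len(count)),
                      low = starts, high = starts + width,
                      stringsAsFactors = FALSE)
  structure(list(bands = bands, bin_width = bin_width,
                 exclusions = exclusions), class = "acfc_band_scheme")
}

#' @export
print.acfc_band_scheme <- function(x, ...) {
  cat(sprintf("<Band scheme: %d bands of %g Hz, %d bins each>\n",
              nrow(x$bands), x$bands$high[1] - x$bands$low[1],
              length(band_bins(x, 1))))
  print(x$bands)
  invisible(x)
}

#' Spectral bin frequencies owned by one band
#'
#' Half-open convention: bins `f` with `low <= f < low + width`.
#'
#' @param scheme An `acfc_band_scheme`.
#' @param m Band index.
#' @return Numeric vector of bin lower-edge frequencies (Hz).
#' @export
band_bins <- function(scheme, m) {
  b <- scheme$bands[m, ]
  seq(b$low, b$high - scheme$bin_width, by = scheme$bin_width)
}

# Hamming taper (periodic form is irrelevant at these lengths; symmetric)
taper_window <- function(n, taper = c("hamming", "rect")) {
  taper <- match.arg(taper)
  if (taper == "rect") return(rep(1, n))
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

#' Single-window spectral power estimate
#'
#' Power spectrum of one analysis window, treated as a single tapered
#' segment (a short-time Fourier transform slice). Power is accumulated
#' into half-open frequency bins `[f, f + bin_width)` covering
#' `[fmin, fmax)`; with the defaults (2-s window, 0.5 Hz bins, 10-250 Hz)
#' this yields 480 power values. Scaling is such that the sum of all bins
#' over the full spectrum approximates the mean squared signal value
#' (taper-compensated), so in-band power obeys Parseval's relation.
#'
#' @param window_samples Numeric vector; one analysis window.
#' @param rate Sampling rate (samples/s); must be at least `2 * fmax`.
#' @param bin_width Output bin width in Hz. The window must be at least
#'   `1 / bin_width` seconds long.
#' @param fmin,fmax Analysis range in Hz (half-open `[fmin, fmax)`).
#' @param taper `"hamming"` (default) or `"rect"`.
#' @return An object of class `acfc_spectrum`: `freqs` (bin lower edges),
#'   `power` (non-negative), `window_center` (seconds, NA if unknown).
#' @export
spectral_power <- function(window_samples, rate, bin_width = 0.5,
                           fmin = 10, fmax = 250, taper = "hamming") {
  n <- length(window_samples)
  if (n / rate < 1 / bin_width - 1e-9) {
    stop("spectral_power: window too short for the requested bin_width")
  }
  if (rate < 2 * fmax) {
    stop("spectral_power: rate must be at least 2 * fmax")
  }
  w <- taper_window(n, taper)
  ff <- (seq_len(n %/% 2 + 1) - 1) * rate / n   # one-sided FFT frequencies
  X <- stats::fft(w * window_samples)[seq_along(ff)]
  pw <- (Mod(X)^2) / (n * sum(w^2))
  dbl <- rep(2, length(ff)); dbl[1] <- 1
  if (n %% 2 == 0) dbl[length(ff)] <- 1
  pw <- pw * dbl
  edges <- seq(fmin, fmax - bin_width, by = bin_width)
  sel <- ff >= fmin & ff < fmax
  idx <- floor((ff[sel] - fmin) / bin_width + 1e-9) + 1L
  power <- numeric(length(edges))
  acc <- rowsum(pw[sel], idx)
  power[as.integer(rownames(acc))] <- acc[, 1]
  structure(list(freqs = edges, power = power, window_center = NA_real_),
            class = "acfc_spectrum")
}

#' EMG band-power time series
#'
#' Slides a window of `window` seconds in steps of `step` seconds over an
#' EMG recording and, for every window, sums the spectral power over the
#' bins of each band of the scheme: `P(F_m, t_i) = sum of S(f_j, t_i)` over
#' bins `f_j` in band `F_m`. Only fully contained windows are emitted and
#' timestamps refer to window centres, so a 60-s recording analysed with a
#' 2-s window and 1-s step yields 59 points per band at t = 1, 2, ..., 59 s.
#'
#' @param rec An EMG [recording()].
#' @param scheme An [make_band_scheme()] scheme.
#' @param window Window length in seconds (must hold at least 500 samples).
#' @param step Step between window starts in seconds; sets the temporal
#'   resolution of the output series.
#' @param taper Taper passed to the spectral estimator.
#' @return List of `acfc_band_power` series, one per band, each with
#'   fields `muscle_id`, `band_label`, `times`, `values`, `step`,
#'   `window_length`, `normalized`.
#' @export
band_power_series <- function(rec, scheme = make_band_scheme(),
                              window = 2, step = 1, taper = "hamming") {
  if (rec$kind != "emg") stop("band_power_series: recording kind must be 'emg'")
  rate <- rec$rate
  if (max(scheme$bands$high) > rate / 2) {
    stop("band_power_series: band scheme exceeds Nyquist")
  }
  wlen <- round(window * rate)
  slen <- round(step * rate)
  if (wlen < 500) {
    stop("band_power_series: window must contain at least 500 samples")
  }
  n <- length(rec$samples)
  if (n < wlen) stop("band_power_series: recording shorter than one window")
  nw <- (n - wlen) %/% slen + 1L
  starts <- (seq_len(nw) - 1L) * slen + 1L
  w <- taper_window(wlen, taper)
  norm <- wlen * sum(w^2)
  # windowed FFTs as one matrix operation
  M <- vapply(starts, function(s) rec$samples[s:(s + wlen - 1L)] * w,
              numeric(wlen))
  X <- stats::mvfft(M)
  nf <- wlen %/% 2 + 1L
  pw <- Mod(X[seq_len(nf), , drop = FALSE])^2 / norm
  dbl <- rep(2, nf); dbl[1] <- 1
  if (wlen %% 2 == 0) dbl[nf] <- 1
  pw <- pw * dbl
  ff <- (seq_len(nf) - 1) * rate / wlen
  times <- rec$start_time + (starts - 1) / rate + window / 2
  out <- vector("list", nrow(scheme$bands))
  names(out) <- scheme$bands$label
  for (m in seq_len(nrow(scheme$bands))) {
    b <- scheme$bands[m, ]
    sel <- ff >= b$low - 1e-9 & ff < b$high - 1e-9
    vals <- colSums(pw[sel, , drop = FALSE])
    out[[m]] <- structure(
      list(muscle_id = rec$channel_id, band_label = b$label,
           times = times, values = vals, step = step,
           window_length = window, normalized = FALSE),
      class = "acfc_band_power")
  }
  out
}

#' @export
print.acfc_band_power <- function(x, ...) {
  cat(sprintf("<Band power %s/%s: %d points, step %g s, window %g s%s>\n",
              x$muscle_id, x$band_label, length(x$values), x$step,
              x$window_length, if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Globally z-score a band-power series
#'
#' Normalizes the whole series to zero mean and unit sample standard
#' deviation, removing absolute amplitude differences across muscles,
#' bands and systems before the global coupling analysis.
#'
#' @param series An `acfc_band_power` (or `acfc_rate_series`).
#' @return The series with `values` standardized and `normalized = TRUE`.
#' @export
zscore_global <- function(series) {
  v <- series$values
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) {
    stop(sprintf("zscore_global: series '%s' has zero variance (dead channel?)",
                 paste(c(series$muscle_id, series$band_label, series$kind),
                       collapse = "/")))
  }
  series$values <- (v - mean(v)) / s
  series$normalized <- TRUE
  series
}

#' Remove a linear trend from a series
#'
#' Least-squares linear detrending (intercept and slope removed), used as a
#' control analysis for protocols that induce slow monotonic drifts in
#' spectral power (e.g. incremental ramps to exhaustion).
#'
#' @param series An `acfc_band_power` or `acfc_rate_series`.
#' @return The series with residual values after removing the fitted line.
#' @export
detrend_series <- function(series) {
  v <- series$values
  if (length(v) < 3) stop("detrend_series: need at least 3 points")
  t <- seq_along(v) - mean(seq_along(v))
  slope <- sum(t * (v - mean(v))) / sum(t^2)
  series$values <- v - mean(v) - slope * t
  series
}
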