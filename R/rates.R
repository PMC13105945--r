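new_rate_series <- function(kind, times, values, step) {
  structure(list(kind = kind, times = times, values = values, step = step),
            class = "acfc_rate_series")
}

#' @export
print.acfc_rate_series <- function(x, ...) {
  cat(sprintf("<Rate series [%s]: %d points, step %g s, mean %.1f /min>\n",
              x$kind, length(x$values), x$step, mean(x$values)))
  invisible(x)
}

#' @export
print.acfc_peak_train <- function(x, ...) {
  cat(sprintf("<Peak train: %d peaks over %.1f s>\n", length(x$peak_times),
              if (length(x$peak_times)) diff(range(x$peak_times)) else 0))
  invisible(x)
}

# local maxima with topographic prominence and a minimum spacing
find_peaks <- function(x, min_prominence = 0, min_distance = 1L) {
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(p) {
    lmin <- x[p]; i <- p
    while (i > 1L && x[i] <= x[p]) { i <- i - 1L; lmin <- min(lmin, x[i]) }
    rmin <- x[p]; i <- p
    while (i < length(x) && x[i] <= x[p]) { i <- i + 1L; rmin <- min(rmin, x[i]) }
    x[p] - max(lmin, rmin)
  }, 0)
  cand <- cand[prom >= min_prominence]
  if (!length(cand)) return(integer(0))
  # greedy strongest-first enforcement of the spacing constraint
  keep <- logical(length(cand))
  ord <- order(x[cand], decreasing = TRUE)
  taken <- integer(0)
  for (j in ord) {
    if (!length(taken) || all(abs(cand[j] - taken) >= min_distance)) {
      keep[j] <- TRUE
      taken <- c(taken, cand[j])
    }
  }
  sort(cand[keep])
}

#' Detect R peaks in an EKG recording (Pan-Tompkins)
#'
#' The classic QRS detector: band-pass (5-15 Hz), differentiation, squaring
#' and moving-window integration (150 ms), followed by adaptive two-level
#' thresholding of integration peaks with a 250-ms refractory period. Each
#' accepted detection is refined to the extremum of the band-passed signal
#' in its neighbourhood, so peak times are accurate to a few milliseconds
#' on clean signals.
#'
#' @param rec An EKG [recording()] sampled at 200 Hz or more.
#' @return An `acfc_peak_train` with strictly increasing `peak_times`
#'   (seconds). A signal with no detectable QRS yields an empty train with
#'   a warning.
#' @export
detect_r_peaks <- function(rec) {
  if (rec$kind != "ekg") stop("detect_r_peaks: recording kind must be 'ekg'")
  if (rec$rate < 200) stop("detect_r_peaks: rate must be at least 200 Hz")
  fs <- rec$rate
  x <- rec$samples
  if (all(x == x[1])) {
    warning("detect_r_peaks: flat signal, no peaks found")
    return(structure(list(peak_times = numeric(0)), class = "acfc_peak_train"))
  }
  bp <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xf <- filtfilt_padded(bp, x, fs, 5)
  dx <- c(0, diff(xf)) * fs
  sq <- dx^2
  wi <- max(1L, round(0.150 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / wi, wi), sides = 1))
  integ[is.na(integ)] <- 0
  refr <- round(0.25 * fs)
  cand <- find_peaks(integ, min_prominence = 0, min_distance = refr)
  if (!length(cand)) {
    warning("detect_r_peaks: no peaks found")
    return(structure(list(peak_times = numeric(0)), class = "acfc_peak_train"))
  }
  # adaptive signal/noise levels (Pan-Tompkins running estimates)
  init <- integ[seq_len(min(length(integ), round(2 * fs)))]
  spki <- max(init); npki <- mean(init)
  accepted <- integer(0)
  for (p in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (integ[p] > thr) {
      accepted <- c(accepted, p)
      spki <- 0.125 * integ[p] + 0.875 * spki
    } else {
      npki <- 0.125 * integ[p] + 0.875 * npki
    }
  }
  if (!length(accepted)) {
    warning("detect_r_peaks: no peaks above threshold")
    return(structure(list(peak_times = numeric(0)), class = "acfc_peak_train"))
  }
  # integration peaks lag the R wave by roughly the integration window;
  # refine on the band-passed signal
  half <- round(0.2 * fs)
  ridx <- vapply(accepted, function(p) {
    lo <- max(1L, p - half); hi <- min(length(xf), p + round(0.05 * fs))
    as.integer(lo + which.max(abs(xf[lo:hi])) - 1L)
  }, 0L)
  ridx <- sort(unique(ridx))
  # enforce the physiological floor on inter-peak intervals
  keep <- c(TRUE, diff(ridx) > 0.25 * fs)
  ridx <- ridx[keep]
  structure(list(peak_times = rec$start_time + (ridx - 1) / fs),
            class = "acfc_peak_train")
}

#' Instantaneous heart-rate series from R peaks
#'
#' Each R-R interval yields one instantaneous rate 60/RR (beats/min)
#' assigned at the later peak; cubic-spline interpolation then resamples
#' the beat-indexed values onto a uniform grid whose timestamps are exact
#' multiples of `step`, aligning them with band-power window centres.
#'
#' @param peaks An `acfc_peak_train` with at least 3 peaks.
#' @param step Output resolution in seconds (default 1).
#' @param clamp Physiological bounds in beats/min; spline excursions are
#'   clipped to this range.
#' @return An `acfc_rate_series` of kind `"hr"`.
#' @export
hr_series <- function(peaks, step = 1, clamp = c(25, 250)) {
  pt <- peaks$peak_times
  if (length(pt) < 3) stop("hr_series: need at least 3 peaks")
  rr <- diff(pt)
  hr <- 60 / rr
  tb <- pt[-1]
  grid <- seq(ceiling(tb[1] / step) * step, floor(tb[length(tb)] / step) * step,
              by = step)
  if (!length(grid)) stop("hr_series: peak train too short for the grid step")
  f <- stats::splinefun(tb, hr, method = "natural")
  v <- pmin(pmax(f(grid), clamp[1]), clamp[2])
  new_rate_series("hr", grid, v, step)
}

#' Correct rate artifacts with a local two-SD rule
#'
#' A point whose value deviates from the mean of its local window (centred,
#' including the point) by more than `k` standard deviations of that window
#' is replaced by the window mean. Statistics are computed on the original
#' series in a single pass, so the result is order-independent.
#'
#' @param rate An `acfc_rate_series`.
#' @param window Window length in seconds (default 10); must exceed
#'   `3 * step`.
#' @param k Threshold in SD multiples (default 2).
#' @return The corrected `acfc_rate_series`.
#' @export
correct_artifacts <- function(rate, window = 10, k = 2) {
  if (window <= 3 * rate$step) stop("correct_artifacts: window must exceed 3 * step")
  v <- rate$values
  t <- rate$times
  half <- window / 2
  out <- v
  for (i in seq_along(v)) {
    idx <- which(t >= t[i] - half & t <= t[i] + half)
    m <- mean(v[idx])
    s <- stats::sd(v[idx])
    if (is.finite(s) && s > 0 && abs(v[i] - m) > k * s) out[i] <- m
  }
  rate$values <- out
  rate
}

# block-mean decimation of a respiratory channel to ~25 Hz for rate work;
# when a step is given, the decimated rate is chosen so the step maps to a
# whole number of samples (keeps output timestamps on the step grid)
decimate_resp <- function(rec, target = 25, step = NULL) {
  block <- max(1L, floor(rec$rate / target))
  if (!is.null(step)) {
    while (block > 1L) {
      fs <- rec$rate / block
      if (abs(fs * step - round(fs * step)) < 1e-9) break
      block <- block - 1L
    }
  }
  if (block == 1L) return(list(x = rec$samples, rate = rec$rate))
  n <- (length(rec$samples) %/% block) * block
  x <- colMeans(matrix(rec$samples[seq_len(n)], nrow = block))
  list(x = x, rate = rec$rate / block)
}

#' Breathing-rate series via breath-peak detection
#'
#' Prominence-based detection of individual breath peaks in a clean
#' respiratory waveform; inter-breath intervals are converted to
#' breaths/min and cubic-spline resampled to a uniform grid. Suitable for
#' resting recordings; use [br_tfr()] for movement-contaminated data.
#'
#' @param rec A respiratory [recording()].
#' @param step Output resolution in seconds (default 0.5).
#' @param clamp Physiological bounds in breaths/min.
#' @return An `acfc_rate_series` of kind `"br"`.
#' @export
br_from_peaks <- function(rec, step = 0.5, clamp = c(4, 80)) {
  if (rec$kind != "resp") stop("br_from_peaks: recording kind must be 'resp'")
  d <- decimate_resp(rec)
  rng <- stats::quantile(d$x, c(0.05, 0.95))
  prom <- 0.25 * max(diff(rng), 1e-12)
  mind <- max(1L, round(60 / clamp[2] * d$rate))
  pk <- find_peaks(d$x, min_prominence = prom, min_distance = mind)
  if (length(pk) < 3) stop("br_from_peaks: fewer than 3 breaths detected")
  pt <- rec$start_time + (pk - 1) / d$rate
  ib <- diff(pt)
  br <- 60 / ib
  tb <- pt[-1]
  grid <- seq(ceiling(tb[1] / step) * step, floor(tb[length(tb)] / step) * step,
              by = step)
  f <- stats::splinefun(tb, br, method = "natural")
  v <- pmin(pmax(f(grid), clamp[1]), clamp[2])
  new_rate_series("br", grid, v, step)
}

#' Breathing-rate series via windowed spectral ridge extraction
#'
#' Time-frequency estimate of the instantaneous breathing rate: a sliding
#' window (default 20 s, covering several respiratory cycles) is tapered
#' and Fourier transformed, the dominant spectral peak inside the
#' respiratory search band is located with parabolic interpolation on a
#' zero-padded grid, converted to breaths/min, and the resulting series
#' (0.5-s resolution by default) is smoothed with a centred moving average.
#' Windows with no spectral peak inside the search band are flagged and
#' bridged by linear interpolation.
#'
#' @param rec A respiratory [recording()] at least one window long.
#' @param window Window length in seconds (default 20).
#' @param step Window step / output resolution in seconds (default 0.5).
#' @param smooth Moving-average length in seconds (default 2).
#' @param search Frequency search band in Hz (default 0.05-1.0).
#' @return An `acfc_rate_series` of kind `"br"` with timestamps at window
#'   centres.
#' @export
br_tfr <- function(rec, window = 20, step = 0.5, smooth = 2,
                   search = c(0.05, 1.0)) {
  if (rec$kind != "resp") stop("br_tfr: recording kind must be 'resp'")
  d <- decimate_resp(rec, target = max(25, 4 * search[2]), step = step)
  fs <- d$rate
  wlen <- round(window * fs)
  slen <- max(1L, round(step * fs))
  n <- length(d$x)
  if (n < wlen) stop("br_tfr: recording shorter than one window")
  nw <- (n - wlen) %/% slen + 1L
  starts <- (seq_len(nw) - 1L) * slen + 1L
  w <- taper_window(wlen, "hamming")
  nfft <- 4L * wlen                       # zero-padding refines the ridge grid
  ff <- (seq_len(nfft %/% 2 + 1) - 1) * fs / nfft
  band <- which(ff >= search[1] & ff <= search[2])
  freqs <- vapply(starts, function(s) {
    seg <- d$x[s:(s + wlen - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(c(seg, numeric(nfft - wlen)))[seq_along(ff)])^2
    pb <- P[band]
    k <- which.max(pb)
    if (!is.finite(pb[k]) || pb[k] <= 0) return(NA_real_)
    # parabolic interpolation around the peak bin
    j <- band[k]
    if (j > 1 && j < length(ff)) {
      num <- P[j - 1] - P[j + 1]
      den <- P[j - 1] - 2 * P[j] + P[j + 1]
      delta <- if (den != 0) 0.5 * num / den else 0
      delta <- max(-0.5, min(0.5, delta))
      (j - 1 + delta) * fs / nfft
    } else {
      ff[j]
    }
  }, 0)
  times <- rec$start_time + (starts - 1) / fs + window / 2
  br <- freqs * 60
  if (anyNA(br)) {
    ok <- which(!is.na(br))
    if (!length(ok)) stop("br_tfr: no spectral peak found in any window")
    br <- stats::approx(times[ok], br[ok], xout = times, rule = 2)$y
  }
  k <- max(1L, round(smooth / step))
  br <- moving_average(br, k)
  new_rate_series("br", times, br, step)
}

# centred moving average with shrinking edge windows
moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  half_lo <- (k - 1L) %/% 2L
  half_hi <- k %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(1L, seq_len(n) - half_lo)
  hi <- pmin(n, seq_len(n) + half_hi)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
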