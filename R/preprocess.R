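#' Zero-phase band-pass filter
#'
#' Conditions a raw channel with a Butterworth band-pass applied
#' forward-backward (zero phase), so that filtering does not shift the
#' timing relationships that the equal-time coupling analysis depends on.
#' Recommended pass bands: 5-250 Hz for EMG, 0.5-150 Hz for EKG. The
#' high-pass and low-pass halves are applied as a cascade, which is
#' numerically robust when the lower cut-off sits far below Nyquist.
#'
#' @param rec A [recording()].
#' @param low_cut,high_cut Pass-band edges in Hz; `0 <= low_cut < high_cut`
#'   and `high_cut` below Nyquist.
#' @param order Butterworth order for each cascade half (default 4).
#' @return A filtered `Recording` of identical length and kind.
#' @export
#' @examples
#' r <- recording(rnorm(2000), 1000, "emg")
#' f <- bandpass(r, 5, 250)
bandpass <- function(rec, low_cut, high_cut, order = 4) {
  nyq <- rec$rate / 2
  if (!(low_cut >= 0 && low_cut < high_cut)) {
    stop("bandpass: need 0 <= low_cut < high_cut")
  }
  if (high_cut >= nyq) {
    stop(sprintf("bandpass: high_cut (%g Hz) must be below Nyquist (%g Hz)",
                 high_cut, nyq))
  }
  x <- rec$samples
  if (low_cut > 0) {
    hp <- signal::butter(order, low_cut / nyq, type = "high")
    x <- filtfilt_padded(hp, x, rec$rate, low_cut)
  }
  lp <- signal::butter(order, high_cut / nyq, type = "low")
  x <- filtfilt_padded(lp, x, rec$rate, high_cut)
  recording(x, rec$rate, rec$kind, rec$channel_id, rec$start_time)
}

#' Zero-phase notch (band-stop) filter
#'
#' Removes mains interference with a Butterworth band-stop of the given
#' width centred on the grid frequency (60 Hz in the Americas, 50 Hz in
#' most of Europe), applied forward-backward.
#'
#' @param rec A [recording()].
#' @param center Notch centre frequency in Hz (below Nyquist).
#' @param width Stop-band width in Hz (default 1).
#' @param order Butterworth order (default 2 per cascade direction; a
#'   narrow high-order stop band is numerically fragile).
#' @return A filtered `Recording` of identical length and kind.
#' @export
notch <- function(rec, center, width = 1, order = 2) {
  nyq <- rec$rate / 2
  if (width <= 0) stop("notch: width must be > 0")
  if (center >= nyq) {
    stop(sprintf("notch: center (%g Hz) must be below Nyquist (%g Hz)",
                 center, nyq))
  }
  w <- c(center - width / 2, center + width / 2) / nyq
  flt <- signal::butter(order, w, type = "stop")
  x <- filtfilt_padded(flt, rec$samples, rec$rate, width)
  recording(x, rec$rate, rec$kind, rec$channel_id, rec$start_time)
}

# forward-backward filtering with odd-reflection padding at both ends to
# suppress startup transients; pad length scales with the slowest feature
# the filter must settle on (3 periods of `fknee`), capped at n - 1.
filtfilt_padded <- function(flt, x, rate, fknee) {
  n <- length(x)
  pad <- min(n - 1L, max(50L, ceiling(3 * rate / max(fknee, 0.5))))
  if (pad > 0) {
    head_ref <- 2 * x[1] - x[seq(pad + 1L, 2L)]
    tail_ref <- 2 * x[n] - x[seq(n - 1L, n - pad)]
    xp <- c(head_ref, x, tail_ref)
  } else {
    xp <- x
  }
  yp <- signal::filtfilt(flt, xp)
  yp[seq(pad + 1L, pad + n)]
}

#' Preprocess a recording according to its kind
#'
#' Applies the configured band-pass for the channel kind followed by the
#' notch filter (EMG and EKG only; the respiratory belt is only band-passed).
#'
#' @param rec A [recording()].
#' @param config An [acfc_config()].
#' @return A filtered `Recording`.
#' @export
preprocess_recording <- function(rec, config = acfc_config()) {
  band <- switch(rec$kind, emg = config$emg_band, ekg = config$ekg_band,
                 resp = config$resp_band)
  out <- bandpass(rec, band[1], min(band[2], rec$rate / 2 * 0.99),
                  order = config$filter_order)
  if (rec$kind %in% c("emg", "ekg") && config$notch_center < rec$rate / 2) {
    out <- notch(out, config$notch_center, config$notch_width)
  }
  out
}
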