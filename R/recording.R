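#' Construct a Recording
#'
#' A `Recording` is one uniformly sampled physiological channel: an EMG
#' channel, the EKG channel, or the respiratory-belt channel. All downstream
#' stages (filtering, band power, rate extraction, surrogates) operate on
#' this container.
#'
#' @param samples Numeric vector of signal samples (arbitrary units). Must be
#'   non-empty and free of missing values.
#' @param rate Sampling rate in samples/second; must be positive.
#' @param kind Channel kind: one of `"emg"`, `"ekg"`, `"resp"`.
#' @param channel_id Character label for the channel (e.g. `"LegL"`).
#' @param start_time Time of the first sample in seconds (default 0).
#'
#' @return An object of class `acfc_recording` with fields `channel_id`,
#'   `kind`, `samples`, `rate`, `start_time`.
#' @export
#' @examples
#' r <- recording(sin(2 * pi * 10 * seq(0, 1, by = 1 / 500)), 500, "emg", "LegL")
#' r
recording <- function(samples, rate, kind = c("emg", "ekg", "resp"),
                      channel_id = "ch1", start_time = 0) {
  kind <- match.arg(kind)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("recording: 'samples' must be non-empty")
  if (anyNA(samples)) {
    stop(sprintf("recording: channel '%s' contains missing values (first at sample %d)",
                 channel_id, which(is.na(samples))[1]))
  }
  if (!is.finite(rate) || rate <= 0) stop("recording: 'rate' must be > 0")
  structure(
    list(channel_id = as.character(channel_id), kind = kind,
         samples = samples, rate = as.numeric(rate),
         start_time = as.numeric(start_time)),
    class = "acfc_recording")
}

#' @export
print.acfc_recording <- function(x, ...) {
  cat(sprintf("<Recording '%s' [%s]: %d samples @ %g Hz, %.1f s, start %g s>\n",
              x$channel_id, x$kind, length(x$samples), x$rate,
              length(x$samples) / x$rate, x$start_time))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A `Recording`.
#' @return Duration in seconds.
#' @export
rec_duration <- function(rec) length(rec$samples) / rec$rate

#' Sample times of a recording
#' @param rec A `Recording`.
#' @return Numeric vector of per-sample times in seconds from recording start.
#' @export
rec_times <- function(rec) rec$start_time + (seq_along(rec$samples) - 1) / rec$rate

#' Label a protocol segment
#'
#' Segments name contiguous stretches of the protocol (e.g. Rest, Exercise)
#' over which global coupling matrices are computed.
#'
#' @param name Segment name.
#' @param start,end Segment bounds in seconds; `0 <= start < end`.
#' @return An object of class `acfc_segment`.
#' @export
segment_label <- function(name, start, end) {
  if (!(start >= 0 && start < end)) stop("segment_label: need 0 <= start < end")
  structure(list(name = as.character(name), start = as.numeric(start),
                 end = as.numeric(end)), class = "acfc_segment")
}

#' Crop a recording to a segment
#' @param rec A `Recording`.
#' @param segment An `acfc_segment` (or NULL for no-op).
#' @return A cropped `Recording` with `start_time` set to the segment start.
#' @export
crop_recording <- function(rec, segment) {
  if (is.null(segment)) return(rec)
  i0 <- max(1L, 1L + ceiling((segment$start - rec$start_time) * rec$rate))
  i1 <- min(length(rec$samples), 1L + floor((segment$end - rec$start_time) * rec$rate))
  if (i1 - i0 < 1L) stop("crop_recording: segment does not overlap recording")
  recording(rec$samples[i0:i1], rec$rate, rec$kind, rec$channel_id,
            start_time = rec$start_time + (i0 - 1L) / rec$rate)
}

#' Default pipeline configuration
#'
#' Collects every tunable parameter of the pipeline in one validated list:
#' filter settings per channel kind, the spectral band scheme, window/step
#' lengths for the global (2 s / 1 s), dynamic (6 s / 3 s) and respiratory
#' (20 s / 0.5 s) analyses, lag policy, link-class breakpoints, DFA
#' settings, the coupling-histogram bin width `dc`, and the random seed.
#'
#' @param ... Named overrides of any default element.
#' @return An object of class `acfc_config` (a named list).
#' @export
#' @examples
#' cfg <- acfc_config(dynamic_window = 12, dynamic_step = 6)
#' cfg$dynamic_window
acfc_config <- function(...) {
  cfg <- list(
    emg_band = c(5, 250), ekg_band = c(0.5, 150), resp_band = c(0.05, 2),
    notch_center = 60, notch_width = 1, filter_order = 4,
    band_low = 10, band_width = 19.5, band_count = 10, bin_width = 0.5,
    band_exclusions = list(c(50, 65)),
    spec_fmin = 10, spec_fmax = 250,
    global_window = 2, global_step = 1,
    dynamic_window = 6, dynamic_step = 3,
    resp_window = 20, resp_step = 0.5,
    hr_step = 1, br_window = 20, br_step = 0.5, br_smooth = 2,
    br_search = c(0.05, 1.0),
    hr_clamp = c(25, 250), br_clamp = c(4, 80),
    artifact_window = 10, artifact_k = 2,
    lag = 0, lag_scan = 0,
    link_classes = "methods",
    dfa_order = 1, dfa_n_scales = 15,
    dc = 0.05,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("acfc_config: unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "acfc_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$global_window > cfg$global_step, cfg$global_step > 0,
            cfg$dynamic_window > cfg$dynamic_step, cfg$dynamic_step > 0,
            cfg$resp_window > cfg$resp_step, cfg$resp_step > 0)
  if (!(cfg$dc > 0 && cfg$dc <= 2)) stop("acfc_config: dc must lie in (0, 2]")
  invisible(cfg)
}

#' @export
print.acfc_config <- function(x, ...) {
  cat("<acfc pipeline configuration>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.list(v)) v <- paste(vapply(v, function(z) paste(z, collapse = "-"),
                                      ""), collapse = ", ")
    cat(sprintf("  %-16s %s\n", nm, paste(format(v), collapse = " ")))
  }
  invisible(x)
}
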