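#' Run the full coupling pipeline for one participant
#'
#' Chains every stage for a single participant's recordings: preprocessing
#' (band-pass + notch), EMG band-power extraction with global
#' z-normalization, heart-rate and breathing-rate series, global coupling
#' matrices for every muscle pair and every rate-muscle pair, multiplex
#' network maps, and (optionally) the windowed coupling time series with
#' their histogram and variability statistics.
#'
#' @param emg Named list of EMG [recording()]s.
#' @param ekg Optional EKG [recording()].
#' @param resp Optional respiration [recording()].
#' @param config An [acfc_config()].
#' @param segment Optional [segment_label()] restricting the analysis.
#' @param dynamic If TRUE (default), compute coupling time series and
#'   variability statistics for every link.
#' @param preprocess If TRUE (default), filter the raw recordings first.
#' @return A list with elements `band_power` (z-scored, per muscle), `hr`,
#'   `br`, `matrices` (per pair), `network`, `rate_matrices`,
#'   `rate_networks`, `dynamic` (per pair: coupling series list,
#'   histograms, stats), and `config`.
#' @export
acfc_participant <- function(emg, ekg = NULL, resp = NULL,
                             config = acfc_config(), segment = NULL,
                             dynamic = TRUE, preprocess = TRUE) {
  scheme <- make_band_scheme(config$band_low, config$band_width,
                             config$band_count, config$bin_width,
                             config$band_exclusions)
  prep <- function(r) {
    r <- crop_recording(r, segment)
    if (preprocess) preprocess_recording(r, config) else r
  }
  emg <- lapply(emg, prep)
  bp <- lapply(emg, function(r) {
    lapply(band_power_series(r, scheme, config$global_window,
                             config$global_step), zscore_global)
  })
  out <- list(band_power = bp, config = config)
  pairs <- t(utils::combn(names(emg), 2L))
  out$matrices <- lapply(seq_len(nrow(pairs)), function(q) {
    coupling_matrix(bp[[pairs[q, 1]]], bp[[pairs[q, 2]]], lag = config$lag,
                    segment = segment)
  })
  names(out$matrices) <- paste(pairs[, 1], pairs[, 2], sep = "-")
  out$network <- build_network(out$matrices, config$link_classes)
  if (!is.null(ekg)) {
    hr <- hr_series(detect_r_peaks(prep(ekg)), step = config$hr_step,
                    clamp = config$hr_clamp)
    hr <- correct_artifacts(hr, config$artifact_window, config$artifact_k)
    out$hr <- hr
    hrz <- zscore_global(hr)
    out$rate_matrices$hr <- lapply(names(emg), function(ch) {
      coupling_matrix(hrz, bp[[ch]], lag = config$lag, segment = segment,
                      pair_id = c("Heart", ch))
    })
    names(out$rate_matrices$hr) <- paste0("Heart-", names(emg))
    out$rate_networks$hr <- build_network(out$rate_matrices$hr, "fig6_cardio")
  }
  if (!is.null(resp)) {
    br <- br_tfr(prep(resp), window = config$br_window,
                 step = config$br_step, smooth = config$br_smooth,
                 search = config$br_search)
    out$br <- br
    # respiratory-muscular coupling uses long windows at the BR resolution
    bp_resp <- lapply(emg, function(r) {
      lapply(band_power_series(r, scheme, config$resp_window,
                               config$resp_step), zscore_global)
    })
    brz <- zscore_global(br)
    out$rate_matrices$br <- lapply(names(emg), function(ch) {
      coupling_matrix(brz, bp_resp[[ch]], lag = config$lag, segment = segment,
                      pair_id = c("Resp", ch))
    })
    names(out$rate_matrices$br) <- paste0("Resp-", names(emg))
    out$rate_networks$br <- build_network(out$rate_matrices$br, "fig6_resp")
  }
  if (dynamic) {
    out$dynamic <- list()
    for (q in seq_len(nrow(pairs))) {
      key <- paste(pairs[q, 1], pairs[q, 2], sep = "-")
      cts <- windowed_coupling_set(bp[[pairs[q, 1]]], bp[[pairs[q, 2]]],
                                   window = config$dynamic_window,
                                   step = config$dynamic_step,
                                   lag = config$lag)
      out$dynamic[[key]] <- cts
    }
    if (!is.null(out$hr)) {
      hrz <- zscore_global(out$hr)
      for (ch in names(emg)) {
        out$dynamic[[paste0("Heart-", ch)]] <-
          windowed_coupling_set(hrz, bp[[ch]],
                                window = config$dynamic_window,
                                step = config$dynamic_step, lag = config$lag)
      }
    }
  }
  out
}

#' Variability summary for a set of coupling time series
#'
#' Applies [static_stats()], [histogram_profile()] and [dfa()] to every
#' coupling time series in a list (as produced by
#' [windowed_coupling_set()] or `acfc_participant()$dynamic`).
#'
#' @param cts_list Named list of `acfc_coupling_ts`.
#' @param dc Histogram bin width.
#' @param dfa_min_n Minimum series length before DFA is attempted
#'   (default 16); shorter series get `NA` exponents.
#' @return Data frame: one row per link with the static measures and the
#'   DFA exponent of the coupling series.
#' @export
variability_summary <- function(cts_list, dc = 0.05, dfa_min_n = 16) {
  rows <- lapply(names(cts_list), function(nm) {
    cts <- cts_list[[nm]]
    st <- static_stats(cts)
    alpha <- NA_real_
    v <- cts$values[!is.na(cts$values)]
    if (length(v) >= dfa_min_n) {
      alpha <- tryCatch(dfa(v)$alpha, error = function(e) NA_real_)
    }
    cbind(st, dfa_alpha = alpha)
  })
  do.call(rbind, rows)
}
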