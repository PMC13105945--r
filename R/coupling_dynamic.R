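#' Windowed coupling time series (locally normalized)
#'
#' Slides a window (default 6 s, stepping 3 s) over two aligned series.
#' Within each window both sub-series are normalized separately to zero
#' mean and unit sample SD, and the equal-time zero-lag coefficient is
#' `1/(W-1) * sum of products` of the normalized values — exactly the
#' per-window Pearson correlation. Local normalization preserves the
#' short-timescale co-variation pattern inside each window instead of
#' letting the global amplitude envelope dominate. Windows where either
#' sub-series has zero variance yield a missing value (flagged, not zero).
#'
#' @param a,b Aligned series (band power or rate) sharing the same step.
#' @param window Window length in seconds (default 6); must hold at least
#'   4 samples.
#' @param step Step between windows in seconds (default 3).
#' @param lag Lag in seconds applied to `b` before windowing (default 0).
#' @return An `acfc_coupling_ts` with values at window centres; the number
#'   of windows is `floor((T - window)/step) + 1` for common support of
#'   duration `T`.
#' @export
windowed_coupling <- function(a, b, window = 6, step = 3, lag = 0) {
  al <- align_pair(a, b, lag)
  dt <- a$step
  wlen <- round(window / dt)
  slen <- max(1L, round(step / dt))
  if (wlen < 4) stop("windowed_coupling: window must contain at least 4 samples")
  n <- al$n
  if (n < wlen) stop("windowed_coupling: overlap shorter than one window")
  nw <- (n - wlen) %/% slen + 1L
  starts <- (seq_len(nw) - 1L) * slen + 1L
  vals <- vapply(starts, function(s) {
    xs <- al$x[s:(s + wlen - 1L)]
    ys <- al$y[s:(s + wlen - 1L)]
    sx <- stats::sd(xs); sy <- stats::sd(ys)
    if (sx == 0 || sy == 0) return(NA_real_)
    zx <- (xs - mean(xs)) / sx
    zy <- (ys - mean(ys)) / sy
    sum(zx * zy) / (wlen - 1)
  }, 0)
  vals <- pmin(pmax(vals, -1), 1)
  # window centre = centre time of the samples it covers
  times <- al$times[starts] + (wlen - 1L) * dt / 2
  link_id <- c(series_label(a), series_label(b))
  pair_id <- c(series_system(as_series_list(a)), series_system(as_series_list(b)))
  structure(list(pair_id = pair_id, link_id = link_id, times = times,
                 values = vals, window_length = window, step = step,
                 lag = lag),
            class = "acfc_coupling_ts")
}

series_label <- function(s) {
  if (inherits(s, "acfc_band_power")) s$band_label else toupper(s$kind)
}

#' @export
print.acfc_coupling_ts <- function(x, ...) {
  cat(sprintf("<Coupling time series %s-%s link %s:%s — %d windows (%g s / %g s), %d missing>\n",
              x$pair_id[1], x$pair_id[2], x$link_id[1], x$link_id[2],
              length(x$values), x$window_length, x$step, sum(is.na(x$values))))
  invisible(x)
}

#' All windowed coupling series between two band sets
#'
#' Convenience wrapper producing one coupling time series per link
#' (band-band or rate-band combination): 100 series for a 10-band muscle
#' pair, 10 for a rate-muscle pair.
#'
#' @param a,b Lists of series (or a single rate series), as in
#'   [coupling_matrix()].
#' @inheritParams windowed_coupling
#' @return A flat list of `acfc_coupling_ts`, named `"Fm:Fk"`.
#' @export
windowed_coupling_set <- function(a, b, window = 6, step = 3, lag = 0) {
  a <- as_series_list(a)
  b <- as_series_list(b)
  out <- list()
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      cts <- windowed_coupling(a[[i]], b[[j]], window, step, lag)
      out[[paste(names(a)[i], names(b)[j], sep = ":")]] <- cts
    }
  }
  out
}

#' Histogram profile of a coupling time series
#'
#' Bins the coupling values into fixed bins of width `dc` covering
#' [-1, 1] (40 bins at the default `dc = 0.05`; values of exactly 1 fall
#' in the last bin) and rescales counts by the maximum count so the peak
#' equals 1. Missing windows are excluded; the counts conserve the number
#' of contributing windows.
#'
#' @param cts An `acfc_coupling_ts` with at least one non-missing value.
#' @param dc Bin width in (0, 2] (default 0.05).
#' @return An `acfc_histogram` with `bin_edges`, `counts`, `rescaled`.
#' @export
histogram_profile <- function(cts, dc = 0.05) {
  if (!(dc > 0 && dc <= 2)) stop("histogram_profile: dc must lie in (0, 2]")
  v <- cts$values[!is.na(cts$values)]
  if (!length(v)) stop("histogram_profile: all values missing")
  nb <- ceiling(2 / dc - 1e-9)
  edges <- -1 + dc * seq(0, nb)
  edges[nb + 1] <- max(edges[nb + 1], 1)
  idx <- pmin(findInterval(v, edges, rightmost.closed = TRUE), nb)
  counts <- tabulate(idx, nbins = nb)
  structure(list(bin_edges = edges, counts = counts,
                 rescaled = counts / max(counts)),
            class = "acfc_histogram")
}

#' @export
print.acfc_histogram <- function(x, ...) {
  cat(sprintf("<Coupling histogram: %d bins, %d values, mode bin [%.2f, %.2f)>\n",
              length(x$counts), sum(x$counts),
              x$bin_edges[which.max(x$counts)],
              x$bin_edges[which.max(x$counts) + 1]))
  invisible(x)
}

#' @export
plot.acfc_histogram <- function(x, ...) {
  mid <- (utils::head(x$bin_edges, -1) + x$bin_edges[-1]) / 2
  graphics::plot(mid, x$rescaled, type = "h", lwd = 3,
                 xlab = "coupling C", ylab = "rescaled count",
                 xlim = c(-1, 1), ...)
  invisible(x)
}
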