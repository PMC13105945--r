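#' Static variability statistics of a coupling time series
#'
#' Standard deviation (magnitude of coupling fluctuations), kurtosis
#' (spikiness: how often extreme fluctuations occur) and skewness
#' (asymmetry: whether strong or weak couplings dominate). Conventions are
#' explicit in the output: SD uses the n-1 denominator; skewness is
#' `m3 / m2^1.5`; kurtosis is reported both in the Pearson convention
#' (normal = 3) and as excess kurtosis (normal = 0). Missing windows are
#' dropped.
#'
#' @param cts An `acfc_coupling_ts` (or any object with `values`); at
#'   least 8 non-missing values are required for higher moments.
#' @return An `acfc_var_stats` one-row data frame with `pair`, `link`,
#'   `n`, `sd`, `skewness`, `kurtosis_pearson`, `kurtosis_excess`,
#'   `sd_convention`, `moment_convention`. For a constant series the
#'   higher moments are `NA` (flagged, not zero).
#' @export
static_stats <- function(cts) {
  v <- cts$values[!is.na(cts$values)]
  if (length(v) < 8) stop("static_stats: need at least 8 non-missing values")
  n <- length(v)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  s <- stats::sd(v)
  if (m2 == 0) {
    skew <- NA_real_; kurt <- NA_real_
  } else {
    skew <- mean((v - m)^3) / m2^1.5
    kurt <- mean((v - m)^4) / m2^2
  }
  structure(data.frame(
    pair = paste(cts$pair_id %||% c("", ""), collapse = "-"),
    link = paste(cts$link_id %||% c("", ""), collapse = ":"),
    n = n, sd = s, skewness = skew,
    kurtosis_pearson = kurt, kurtosis_excess = kurt - 3,
    sd_convention = "sample (n-1)",
    moment_convention = "population moments m3/m2^1.5, m4/m2^2",
    stringsAsFactors = FALSE), class = c("acfc_var_stats", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detrended fluctuation analysis
#'
#' Quantifies scale-invariant temporal structure in a (possibly
#' nonstationary) series. The profile `Y(k) = cumulative sum of (x - mean)`
#' is divided, at every scale `n`, into non-overlapping windows of length
#' `n`; a polynomial of order `detrend_order` is fitted in each window and
#' `F(n)` is the root-mean-square deviation of the profile from these
#' local trends. Both a forward and a reversed pass over the profile are
#' averaged so trailing samples are not discarded. A power law
#' `F(n) ~ n^alpha` identifies the scaling exponent: alpha = 0.5 for
#' uncorrelated white noise, 1.5 for a random walk, between 0.5 and 1.5
#' for persistent correlations, below 0.5 for anti-correlations.
#'
#' @param series Numeric vector, or an object with a `values` field
#'   (missing values dropped).
#' @param scales Integer scales (window lengths in samples). Default:
#'   about 15 log-spaced scales from 4 to N/4. Scales above N/4 are
#'   dropped with a warning; fewer than 4 usable scales is an error.
#' @param detrend_order Polynomial order of the local detrending
#'   (default 1, i.e. DFA-1).
#' @param fit_range Optional `c(n_min, n_max)` restricting the exponent
#'   fit; default is all usable scales.
#' @return An `acfc_dfa`: `scales`, `fluctuation`, `alpha`, `fit_range`,
#'   `detrend_order`.
#' @export
#' @examples
#' set.seed(1)
#' dfa(rnorm(2000))$alpha   # close to 0.5
dfa <- function(series, scales = NULL, detrend_order = 1, fit_range = NULL) {
  x <- if (is.list(series)) series$values else series
  x <- x[!is.na(x)]
  N <- length(x)
  auto <- is.null(scales)
  if (auto) {
    scales <- unique(round(exp(seq(log(4), log(max(5, floor(N / 4))),
                                   length.out = 15))))
  }
  scales <- sort(unique(round(scales)))
  drop <- scales > N / 4 | scales < max(2, detrend_order + 2)
  if (!auto && any(scales > N / 4)) {
    warning("dfa: dropping ", sum(scales > N / 4), " scale(s) above N/4")
  }
  scales <- scales[!drop]
  if (length(scales) < 4) stop("dfa: fewer than 4 usable scales")
  Y <- cumsum(x - mean(x))
  Fn <- vapply(scales, function(n) dfa_fluctuation(Y, n, detrend_order), 0)
  if (is.null(fit_range)) fit_range <- range(scales)
  sel <- scales >= fit_range[1] & scales <= fit_range[2] & Fn > 0
  alpha <- if (sum(sel) >= 2) {
    unname(stats::lm.fit(cbind(1, log(scales[sel])), log(Fn[sel]))$coefficients[2])
  } else {
    NA_real_   # degenerate input: the local trends absorb the profile
  }
  structure(list(scales = scales, fluctuation = Fn, alpha = alpha,
                 fit_range = fit_range, detrend_order = detrend_order),
            class = "acfc_dfa")
}

# RMS fluctuation at a single scale: non-overlapping windows, local
# polynomial detrend, forward and reversed passes averaged
dfa_fluctuation <- function(Y, n, order) {
  N <- length(Y)
  m <- N %/% n
  t <- seq_len(n)
  X <- stats::poly(t, degree = order, raw = TRUE)
  X <- cbind(1, X)
  # residual-maker via QR, shared by all windows of this scale
  qrX <- qr(X)
  res2 <- function(seg_mat) {
    # seg_mat: n x m matrix of profile windows
    resid <- qr.resid(qrX, seg_mat)
    colMeans(resid^2)
  }
  fwd <- matrix(Y[seq_len(m * n)], nrow = n)
  rev_ <- matrix(rev(Y)[seq_len(m * n)], nrow = n)
  mean_sq <- mean(c(res2(fwd), res2(rev_)))
  sqrt(mean_sq)
}

#' @export
print.acfc_dfa <- function(x, ...) {
  cat(sprintf("<DFA-%d: alpha = %.3f over scales %d..%d (%d scales)>\n",
              x$detrend_order, x$alpha, min(x$scales), max(x$scales),
              length(x$scales)))
  invisible(x)
}

#' @export
plot.acfc_dfa <- function(x, ...) {
  graphics::plot(x$scales, x$fluctuation, log = "xy", xlab = "scale n",
                 ylab = "F(n)", ...)
  graphics::abline(stats::lm(log10(x$fluctuation) ~ log10(x$scales)),
                   col = "grey50", lty = 2)
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("alpha = %.3f", x$alpha))
  invisible(x)
}

#' Magnitude-sign decomposition of coupling increments
#'
#' Decomposes the increment series `dC(t_i) = C(t_{i+1}) - C(t_i)` into a
#' magnitude series `|dC|` (carrying nonlinear characteristics) and a sign
#' series `sgn(dC)` (carrying linear characteristics); both can be fed to
#' [dfa()]. `sgn(0)` is kept as 0. Missing windows are dropped before
#' differencing and increments that would span such a gap are flagged.
#'
#' @param cts An `acfc_coupling_ts` (or numeric vector) with at least two
#'   values.
#' @return An `acfc_magnitude_sign`: `increments`, `magnitude`, `sign`,
#'   `spans_gap` (logical), `times` (of the leading sample, where known).
#' @export
magnitude_sign <- function(cts) {
  v <- if (is.list(cts)) cts$values else cts
  t <- if (is.list(cts)) cts$times else seq_along(v)
  ok <- !is.na(v)
  if (sum(ok) < 2) stop("magnitude_sign: need at least 2 non-missing values")
  idx <- which(ok)
  v <- v[idx]
  inc <- diff(v)
  gap <- diff(idx) > 1L
  structure(list(increments = inc, magnitude = abs(inc), sign = sign(inc),
                 spans_gap = gap, times = t[idx][-length(idx)]),
            class = "acfc_magnitude_sign")
}

#' @export
print.acfc_magnitude_sign <- function(x, ...) {
  cat(sprintf("<Magnitude-sign series: %d increments (%d spanning gaps), mean |dC| = %.3f>\n",
              length(x$increments), sum(x$spans_gap), mean(x$magnitude)))
  invisible(x)
}
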