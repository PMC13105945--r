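new_coupling_matrix <- function(values, pair_id, lag, segment, n_participants) {
  stopifnot(is.matrix(values))
  structure(list(values = values, pair_id = pair_id, lag = lag,
                 segment = segment, n_participants = n_participants),
            class = "acfc_coupling_matrix")
}

#' @export
print.acfc_coupling_matrix <- function(x, digits = 3, ...) {
  seg <- if (!is.null(x$segment)) paste0(", segment '", x$segment$name, "'") else ""
  cat(sprintf("<Coupling matrix %s-%s (%dx%d), lag %g s%s, n=%s>\n",
              x$pair_id[1], x$pair_id[2], nrow(x$values), ncol(x$values),
              x$lag, seg, x$n_participants))
  print(round(x$values, digits))
  invisible(x)
}

# wrap a single rate series as a one-row "band set"
as_series_list <- function(x) {
  if (inherits(x, "acfc_rate_series")) {
    out <- list(x)
    names(out) <- toupper(x$kind)
    return(out)
  }
  if (inherits(x, "acfc_band_power")) return(stats::setNames(list(x), x$band_label))
  if (!is.list(x)) stop("coupling_matrix: inputs must be series or lists of series")
  nm <- vapply(x, function(s) {
    if (inherits(s, "acfc_band_power")) s$band_label else toupper(s$kind)
  }, "")
  stats::setNames(x, nm)
}

series_system <- function(x) {
  s <- x[[1]]
  if (inherits(s, "acfc_band_power")) s$muscle_id
  else if (s$kind == "hr") "Heart" else "Resp"
}

# trim two uniform series to their common support after shifting b by `lag`
align_pair <- function(a, b, lag = 0) {
  if (abs(a$step - b$step) > 1e-9) {
    stop("coupling: series must share the same step (got ",
         a$step, " and ", b$step, ")")
  }
  step <- a$step
  off <- (b$times[1] - lag - a$times[1]) / step
  if (abs(off - round(off)) > 1e-6) {
    stop("coupling: series time grids are not alignable at this lag")
  }
  off <- round(off)
  ia <- max(1L, 1L + off)
  ib <- max(1L, 1L - off)
  m <- min(length(a$values) - ia, length(b$values) - ib) + 1L
  if (m < 1L) stop("coupling: series do not overlap")
  list(x = a$values[ia:(ia + m - 1L)], y = b$values[ib:(ib + m - 1L)],
       times = a$times[ia:(ia + m - 1L)], n = m)
}

#' Equal-time coupling matrix between two band sets
#'
#' Computes the Pearson cross-correlation between every series of `a`
#' (rows) and every series of `b` (columns) on their trimmed common time
#' support, optionally after shifting `b` by `lag` seconds (`r(lag) =
#' cor(a(t), b(t + lag))`). With two 10-band EMG sets this yields the
#' 10 x 10 inter-muscular matrix (100 values); with a heart- or
#' breathing-rate series as `a` it yields the 1 x 10 rate-muscle matrix.
#'
#' @param a,b A list of `acfc_band_power` series, a single series, or an
#'   `acfc_rate_series`. All series must share the same step and overlap
#'   in time (globally z-scored band-power series are the intended input).
#' @param lag Lag in seconds; must be a multiple of the common step.
#' @param pair_id Character pair label `c(system_a, system_b)`; inferred
#'   from the series when omitted.
#' @param segment Optional `acfc_segment` the matrix refers to.
#' @return An `acfc_coupling_matrix`.
#' @export
coupling_matrix <- function(a, b, lag = 0, pair_id = NULL, segment = NULL) {
  a <- as_series_list(a)
  b <- as_series_list(b)
  if (is.null(pair_id)) pair_id <- c(series_system(a), series_system(b))
  vals <- matrix(NA_real_, length(a), length(b),
                 dimnames = list(names(a), names(b)))
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      al <- align_pair(a[[i]], b[[j]], lag)
      if (al$n < 10) stop("coupling_matrix: overlap shorter than 10 points")
      if (stats::sd(al$x) == 0) {
        stop("coupling_matrix: zero-variance series in row band '", names(a)[i], "'")
      }
      if (stats::sd(al$y) == 0) {
        stop("coupling_matrix: zero-variance series in column band '", names(b)[j], "'")
      }
      vals[i, j] <- stats::cor(al$x, al$y)
    }
  }
  new_coupling_matrix(vals, pair_id, lag, segment, 1L)
}

#' Scan lags and return the best one
#'
#' Evaluates the Pearson coupling of two series at each candidate lag and
#' returns the lag maximizing it. Ties are broken toward the smallest
#' absolute lag, then negative before positive.
#'
#' @param a,b Single series (band power or rate).
#' @param lag_candidates Numeric vector of lags in seconds (multiples of
#'   the common step, each within 25% of the overlap length).
#' @return List with `lag`, `r`, and the full `scan` data frame.
#' @export
best_lag <- function(a, b, lag_candidates = c(-3, -2, -1, 0, 1, 2, 3)) {
  if (inherits(a, "acfc_rate_series") || inherits(a, "acfc_band_power")) a <- a
  ov <- align_pair(a, b, 0)
  span <- ov$n * a$step
  if (any(abs(lag_candidates) > 0.25 * span)) {
    stop("best_lag: candidate lags must stay within 25% of the overlap length")
  }
  rs <- vapply(lag_candidates, function(l) {
    al <- align_pair(a, b, l)
    stats::cor(al$x, al$y)
  }, 0)
  ord <- order(abs(lag_candidates), lag_candidates)
  best <- ord[which.max(rs[ord] + 0)]
  best <- ord[which(rs[ord] >= max(rs) - 1e-15)[1]]
  list(lag = lag_candidates[best], r = rs[best],
       scan = data.frame(lag = lag_candidates, r = rs))
}

#' Group-average coupling matrices
#'
#' Element-wise arithmetic mean of per-participant coupling matrices
#' sharing the same pair, shape and lag (raw r values, no Fisher
#' transform). Cells missing for some participants (e.g. a dead channel)
#' are mean-ignored, with the participant count recorded.
#'
#' @param matrices List of `acfc_coupling_matrix` objects.
#' @param fisher If TRUE, average in Fisher-z space and back-transform.
#' @return An `acfc_coupling_matrix` with `n_participants` set.
#' @export
group_average <- function(matrices, fisher = FALSE) {
  stopifnot(length(matrices) >= 1L)
  ref <- matrices[[1]]
  for (m in matrices) {
    if (!identical(dim(m$values), dim(ref$values)) ||
        !identical(m$pair_id, ref$pair_id) || m$lag != ref$lag) {
      stop("group_average: matrices must share pair_id, shape and lag")
    }
  }
  arr <- simplify2array(lapply(matrices, function(m) {
    if (fisher) atanh(pmin(pmax(m$values, -1 + 1e-15), 1 - 1e-15)) else m$values
  }))
  avg <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  if (fisher) avg <- tanh(avg)
  dimnames(avg) <- dimnames(ref$values)
  new_coupling_matrix(avg, ref$pair_id, ref$lag, ref$segment,
                      length(matrices))
}

#' Link-strength class presets
#'
#' Named breakpoint sets used to classify links when drawing network maps.
#' `methods` is the generic example stratification
#' (0.20/0.35/0.50/0.65); `fig6_intermuscular` (0.05/0.15/0.25/0.35),
#' `fig6_cardio` (0/0.10/0.20/0.30) and `fig6_resp`
#' (0.15/0.30/0.45/0.60) are the context-specific sets used for
#' inter-muscular, cardio-muscular and respiratory-muscular networks. The
#' stratification is presentational and should be adapted to the data.
#'
#' @return Named list of ascending numeric breakpoints.
#' @export
link_class_presets <- function() {
  list(methods = c(0.20, 0.35, 0.50, 0.65),
       fig6_intermuscular = c(0.05, 0.15, 0.25, 0.35),
       fig6_cardio = c(0.00, 0.10, 0.20, 0.30),
       fig6_resp = c(0.15, 0.30, 0.45, 0.60))
}

link_class_labels <- c("below-threshold", "weak", "intermediate",
                       "strong", "very strong")

classify_strength <- function(r, breaks) {
  link_class_labels[findInterval(r, breaks) + 1L]
}

#' Build a multiplex network map from coupling matrices
#'
#' Turns one coupling matrix per system pair into a single multiplex
#' node-link structure: nodes are (system, frequency band) pairs, every
#' matrix cell becomes a link whose strength is the coupling coefficient,
#' and each link is classified against the breakpoints (weak /
#' intermediate / strong / very strong; values below the lowest breakpoint
#' are "below-threshold").
#'
#' @param matrices List of `acfc_coupling_matrix` objects (one per pair).
#' @param thresholds Either a preset name from [link_class_presets()] or a
#'   strictly increasing numeric vector of four breakpoints.
#' @return An `acfc_network` with `nodes`, `links` and `class_thresholds`.
#' @export
build_network <- function(matrices, thresholds = "methods") {
  if (is.character(thresholds)) {
    thresholds <- link_class_presets()[[match.arg(thresholds,
                                                  names(link_class_presets()))]]
  }
  if (any(diff(thresholds) <= 0)) {
    stop("build_network: thresholds must be strictly increasing")
  }
  if (inherits(matrices, "acfc_coupling_matrix")) matrices <- list(matrices)
  nodes <- unique(do.call(rbind, lapply(matrices, function(m) {
    rbind(data.frame(system = m$pair_id[1], band = rownames(m$values)),
          data.frame(system = m$pair_id[2], band = colnames(m$values)))
  })))
  rownames(nodes) <- NULL
  links <- do.call(rbind, lapply(matrices, function(m) {
    g <- expand.grid(band_a = rownames(m$values), band_b = colnames(m$values),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    data.frame(system_a = m$pair_id[1], band_a = g$band_a,
               system_b = m$pair_id[2], band_b = g$band_b,
               strength = as.vector(m$values[cbind(g$band_a, g$band_b)]),
               stringsAsFactors = FALSE)
  }))
  links$class <- classify_strength(links$strength, thresholds)
  rownames(links) <- NULL
  structure(list(nodes = nodes, links = links,
                 class_thresholds = thresholds), class = "acfc_network")
}

#' @export
print.acfc_network <- function(x, ...) {
  cat(sprintf("<Network map: %d nodes, %d links>\n", nrow(x$nodes),
              nrow(x$links)))
  print(table(factor(x$links$class, levels = link_class_labels)))
  invisible(x)
}

#' Mean link strength per system pair
#'
#' Bar-chart style summary of a network: the average link strength of each
#' sub-network (system pair).
#'
#' @param net An `acfc_network`.
#' @return Data frame with `pair`, `mean_strength`, `n_links`.
#' @export
network_pair_summary <- function(net) {
  key <- paste(net$links$system_a, net$links$system_b, sep = "-")
  agg <- stats::aggregate(net$links$strength, list(pair = key),
                          function(v) c(mean(v), length(v)))
  data.frame(pair = agg$pair, mean_strength = agg$x[, 1],
             n_links = as.integer(agg$x[, 2]))
}

#' @export
plot.acfc_coupling_matrix <- function(x, main = NULL, ...) {
  m <- x$values
  if (is.null(main)) main <- paste(x$pair_id, collapse = " - ")
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
                  zlim = c(-1, 1), xlab = "band (second system)",
                  ylab = "band (first system)", axes = FALSE, main = main,
                  col = grDevices::hcl.colors(41, "RdBu", rev = TRUE), ...)
  graphics::axis(1, seq_len(ncol(m)), colnames(m))
  graphics::axis(2, rev(seq_len(nrow(m))), rownames(m))
  graphics::box()
  invisible(x)
}
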