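#' Read a multichannel recording file
#'
#' Reads a delimited text file (comma-separated, mandatory header row, "."
#' decimal) with one column per channel, together with a metadata sidecar
#' declaring the sampling rate and the kind of every column. Any missing or
#' non-numeric cell is an ingestion error naming the offending column.
#'
#' @param path Path to the CSV file.
#' @param meta Either a path to a YAML/JSON sidecar or an inline list. The
#'   metadata must contain `rate` (samples/s) and `channels`, a list of
#'   `list(id =, kind =)` entries covering every column; optional
#'   `start_time` (seconds, default 0).
#' @return A named list of [recording()] objects, one per declared column.
#' @export
read_recording <- function(path, meta) {
  if (!file.exists(path)) stop("read_recording: no such file: ", path)
  meta <- resolve_meta(meta)
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- vapply(meta$channels, function(ch) ch$id, "")
  kinds <- vapply(meta$channels, function(ch) ch$kind, "")
  undeclared <- setdiff(names(df), ids)
  if (length(undeclared)) {
    stop("read_recording: column(s) not declared in metadata: ",
         paste(undeclared, collapse = ", "))
  }
  missing_cols <- setdiff(ids, names(df))
  if (length(missing_cols)) {
    stop("read_recording: declared channel(s) absent from file: ",
         paste(missing_cols, collapse = ", "))
  }
  start_time <- if (is.null(meta$start_time)) 0 else meta$start_time
  out <- vector("list", length(ids))
  names(out) <- ids
  for (i in seq_along(ids)) {
    v <- df[[ids[i]]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("read_recording: column '%s' has a missing/non-numeric value at data row %d",
                   ids[i], bad))
    }
    out[[i]] <- recording(v, meta$rate, kinds[i], ids[i], start_time)
  }
  out
}

resolve_meta <- function(meta) {
  if (is.character(meta) && length(meta) == 1L) {
    if (!file.exists(meta)) stop("read_recording: no such sidecar: ", meta)
    meta <- if (grepl("\\.json$", meta, ignore.case = TRUE)) {
      jsonlite::read_json(meta, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(meta)
    }
  }
  if (is.null(meta$rate) || is.null(meta$channels)) {
    stop("read_recording: metadata must declare 'rate' and 'channels'")
  }
  meta$rate <- as.numeric(meta$rate)
  meta
}

#' Write recordings as CSV plus sidecar
#'
#' Inverse of [read_recording()]: all channels must share rate, start time
#' and length. Samples are written with 17 significant digits so that a
#' write/read round trip is bit-identical.
#'
#' @param recs List of `Recording`s with equal length and rate.
#' @param path Output CSV path; the sidecar is written next to it as
#'   `<path>.meta.yaml`.
#' @param overwrite Overwrite existing files (default FALSE).
#' @return Invisibly, c(csv = path, meta = sidecar path).
#' @export
write_recordings <- function(recs, path, overwrite = FALSE) {
  stopifnot(length(recs) >= 1L)
  ns <- vapply(recs, function(r) length(r$samples), 0L)
  rates <- vapply(recs, function(r) r$rate, 0)
  if (length(unique(ns)) != 1L || length(unique(rates)) != 1L) {
    stop("write_recordings: channels must share length and rate")
  }
  meta_path <- paste0(path, ".meta.yaml")
  if (!overwrite && (file.exists(path) || file.exists(meta_path))) {
    stop("write_recordings: output exists (use overwrite = TRUE): ", path)
  }
  mat <- vapply(recs, function(r) r$samples, numeric(ns[1]))
  cols <- lapply(seq_len(ncol(mat)), function(j) sprintf("%.17g", mat[, j]))
  names(cols) <- vapply(recs, function(r) r$channel_id, "")
  utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
                   row.names = FALSE, quote = FALSE)
  meta <- list(rate = rates[1], start_time = recs[[1]]$start_time,
               channels = unname(lapply(recs, function(r) {
                 list(id = r$channel_id, kind = r$kind)
               })))
  yaml::write_yaml(meta, meta_path)
  invisible(c(csv = path, meta = meta_path))
}

#' Write an analysis bundle to disk
#'
#' Writes every recognised result object in `bundle` under `out_dir` and
#' returns a manifest. Coupling matrices become labelled CSV; networks
#' become GraphML and JSON node-link; rate/band-power/coupling time series,
#' variability statistics, DFA tables and histograms become tidy long-format
#' CSV; a config becomes YAML. Elements must be named; names become file
#' stems.
#'
#' @param bundle Named list of result objects (possibly empty).
#' @param out_dir Output directory (created if needed).
#' @param overwrite Overwrite pre-existing files (default FALSE).
#' @return Data frame manifest with columns `name`, `file`, `stage`.
#' @export
write_outputs <- function(bundle, out_dir, overwrite = FALSE) {
  if (length(bundle) && (is.null(names(bundle)) || any(names(bundle) == ""))) {
    stop("write_outputs: every bundle element must be named")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(name = character(), file = character(),
                         stage = character(), stringsAsFactors = FALSE)
  emit <- function(name, file, stage) {
    manifest[nrow(manifest) + 1L, ] <<- list(name, file, stage)
  }
  target <- function(stem, ext) {
    f <- file.path(out_dir, paste0(stem, ".", ext))
    if (!overwrite && file.exists(f)) {
      stop("write_outputs: output exists (use overwrite = TRUE): ", f)
    }
    f
  }
  for (nm in names(bundle)) {
    x <- bundle[[nm]]
    if (inherits(x, "acfc_coupling_matrix")) {
      f <- target(nm, "csv")
      write_coupling_matrix(x, f)
      emit(nm, f, "coupling_matrix")
    } else if (inherits(x, "acfc_network")) {
      f1 <- target(nm, "graphml"); f2 <- target(nm, "json")
      write_network_graphml(x, f1)
      write_network_json(x, f2)
      emit(nm, f1, "network_graphml")
      emit(nm, f2, "network_json")
    } else if (inherits(x, "acfc_config")) {
      f <- target(nm, "yaml")
      yaml::write_yaml(unclass(x), f)
      emit(nm, f, "config")
    } else if (is.data.frame(x)) {
      f <- target(nm, "csv")
      utils::write.csv(x, f, row.names = FALSE)
      emit(nm, f, "table")
    } else if (!is.null(tdy <- tidy_result(x))) {
      f <- target(nm, "csv")
      utils::write.csv(tdy, f, row.names = FALSE)
      emit(nm, f, class(x)[1])
    } else {
      stop("write_outputs: no writer for object of class ",
           paste(class(x), collapse = "/"), " (element '", nm, "')")
    }
  }
  manifest
}

# long-format representations for series-like results
tidy_result <- function(x) {
  if (inherits(x, "acfc_band_power")) {
    data.frame(muscle = x$muscle_id, band = x$band_label, t = x$times,
               power = x$values)
  } else if (inherits(x, "acfc_rate_series")) {
    data.frame(kind = x$kind, t = x$times, value = x$values)
  } else if (inherits(x, "acfc_coupling_ts")) {
    data.frame(pair = paste(x$pair_id, collapse = "-"),
               link = paste(x$link_id, collapse = ":"),
               t = x$times, r = x$values)
  } else if (inherits(x, "acfc_histogram")) {
    data.frame(bin_low = utils::head(x$bin_edges, -1),
               bin_high = x$bin_edges[-1],
               count = x$counts, rescaled = x$rescaled)
  } else if (inherits(x, "acfc_dfa")) {
    data.frame(n = x$scales, F = x$fluctuation, alpha = x$alpha)
  } else if (inherits(x, "acfc_peak_train")) {
    data.frame(peak_time = x$peak_times)
  } else {
    NULL
  }
}

#' Write a coupling matrix as labelled CSV
#' @param cm An `acfc_coupling_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_coupling_matrix <- function(cm, path) {
  m <- cm$values
  df <- data.frame(band = rownames(m), check.names = FALSE)
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- sprintf("%.17g", m[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a coupling matrix written by [write_coupling_matrix()]
#' @param path CSV path.
#' @param pair_id Optional pair label to attach, e.g. `c("LegL","LegR")`.
#' @return An `acfc_coupling_matrix` (lag/segment metadata not preserved).
#' @export
read_coupling_matrix <- function(path, pair_id = c("A", "B")) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  new_coupling_matrix(m, pair_id = pair_id, lag = 0, segment = NULL,
                      n_participants = NA_integer_)
}

write_network_graphml <- function(net, path) {
  g <- as_igraph_network(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

write_network_json <- function(net, path) {
  nodes <- net$nodes
  links <- net$links
  jsonlite::write_json(
    list(nodes = nodes, links = links,
         class_thresholds = net$class_thresholds),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Convert a NetworkMap to an igraph object
#' @param net An `acfc_network`.
#' @return An `igraph` graph whose vertices are (system, band) nodes and
#'   whose edges carry `weight`, `class` and `significant` attributes.
#' @export
as_igraph_network <- function(net) {
  vnames <- paste(net$nodes$system, net$nodes$band, sep = ".")
  el <- cbind(paste(net$links$system_a, net$links$band_a, sep = "."),
              paste(net$links$system_b, net$links$band_b, sep = "."))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  miss <- setdiff(vnames, igraph::V(g)$name)
  if (length(miss)) g <- igraph::add_vertices(g, length(miss), name = miss)
  igraph::E(g)$weight <- net$links$strength
  igraph::E(g)$class <- net$links$class
  if (!is.null(net$links$significant)) {
    igraph::E(g)$significant <- net$links$significant
  }
  g
}
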