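#' Read a multichannel time-series matrix from delimited text
#'
#' Rows are time samples, columns are channels; a header row supplies
#' channel names (auto-numbered otherwise). Binary series (all values in
#' \{0, 1\}) are detected automatically.
#'
#' @param path file path (CSV or TSV; delimiter auto-detected from the
#'   extension, override with `sep`).
#' @param sep field separator; default `","` for `.csv`, `"\t"` otherwise.
#' @param dt sampling interval in seconds (metadata).
#' @param header whether the first row holds channel names; auto-detected
#'   when NULL.
#' @return A [ts_set].
#' @export
read_timeseries <- function(path, sep = NULL, dt = 1, header = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  first <- readLines(path, n = 1)
  if (is.null(header)) {
    cells <- strsplit(first, sep, fixed = TRUE)[[1]]
    header <- any(is.na(suppressWarnings(as.numeric(cells))))
  }
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))
    stop("non-numeric column(s): ", paste(names(df)[bad], collapse = ", "))
  }
  ts_set(m, dt = dt)
}

#' Read a spike table from two-column delimited text
#'
#' Expects columns (unit_id, time_seconds); a header row is optional.
#'
#' @param path file path.
#' @param sep field separator; auto-detected from the extension by default.
#' @return A data frame with columns `unit` and `time`.
#' @export
read_spikes <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  first <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
  header <- is.na(suppressWarnings(as.numeric(first[2])))
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("spike table needs (unit, time) columns")
  names(df)[1:2] <- c("unit", "time")
  df$time <- as.numeric(df$time)
  df[, 1:2]
}

#' Write a connectivity graph to TSV and/or JSON
#'
#' The TSV holds the edge list (columns source, target, raw_di_nats,
#' raw_gdi_nats, normalized, sign, weight, tau_star_samples; undetermined
#' signs serialize as `NA`). The JSON mirrors the edge list, adds the node
#' array and echoes the resolved configuration for provenance. A
#' write-then-read round trip reproduces the graph.
#'
#' @param graph a `di_graph`.
#' @param tsv_path,json_path output paths (either may be NULL to skip).
#' @return Invisibly, the graph.
#' @export
write_graph <- function(graph, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(graph, "di_graph"))
  if (!is.null(tsv_path)) {
    utils::write.table(graph$edges, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    cfg <- graph$config
    cfg$estimator$classifier <- unclass(cfg$estimator$classifier)
    cfg$estimator <- unclass(cfg$estimator)
    payload <- list(nodes = graph$nodes, edges = graph$edges,
                    config = unclass(cfg))
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(graph)
}

#' Read a connectivity graph edge list written by [write_graph()]
#'
#' @param tsv_path path to the TSV edge list.
#' @param nodes optional node vector; defaults to the union of sources and
#'   targets in the file.
#' @return A `di_graph` (with `config = NULL`).
#' @export
read_graph <- function(tsv_path, nodes = NULL) {
  edges <- utils::read.table(tsv_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = c(source = "character",
                                            target = "character"))
  if (is.null(nodes)) nodes <- unique(c(edges$source, edges$target))
  structure(list(nodes = nodes, edges = edges, config = NULL),
            class = "di_graph")
}
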