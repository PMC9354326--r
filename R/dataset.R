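#' Mixed-type datasets
#'
#' A `dag_dataset` bundles an n x p numeric value matrix (samples in rows,
#' nodes in columns) with a per-column kind, `"continuous"` or `"binary"`.
#' Binary columns must contain only 0 and 1; missing values are rejected
#' (missing-data handling is out of scope). Kinds are fixed for the
#' lifetime of the dataset.
#'
#' @param values numeric matrix or data frame with named columns.
#' @param kinds character vector of length p with values `"continuous"` or
#'   `"binary"`, optionally named by column. When `NULL`, a column whose
#'   values are a subset of \{0, 1\} is inferred binary; an explicit
#'   declaration always wins over inference.
#' @return A `dag_dataset` with fields `values`, `kinds`, `nodes`, `n`.
#' @export
make_dataset <- function(values, kinds = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("V", seq_len(ncol(values)))
  }
  if (anyDuplicated(colnames(values))) stop("duplicate column names")
  if (!is.numeric(values)) stop("dataset values must be numeric")
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop("missing value at row ", bad[1], ", column '",
         colnames(values)[bad[2]], "'")
  }
  nodes <- colnames(values)
  p <- ncol(values)
  if (is.null(kinds)) {
    kinds <- ifelse(apply(values, 2, function(x) all(x %in% c(0, 1))),
                    "binary", "continuous")
  } else {
    if (!is.null(names(kinds))) kinds <- kinds[nodes]
    kinds <- as.character(kinds)
    if (length(kinds) != p) stop("kinds must have one entry per column")
  }
  if (!all(kinds %in% c("continuous", "binary"))) {
    stop("kinds must be 'continuous' or 'binary'")
  }
  names(kinds) <- nodes
  for (j in which(kinds == "binary")) {
    if (!all(values[, j] %in% c(0, 1))) {
      stop("binary column '", nodes[j], "' has values outside {0, 1}")
    }
  }
  structure(list(values = values, kinds = kinds, nodes = nodes,
                 n = nrow(values)),
            class = "dag_dataset")
}

#' @export
print.dag_dataset <- function(x, ...) {
  cat("dag_dataset: ", x$n, " samples x ", length(x$nodes), " nodes (",
      sum(x$kinds == "continuous"), " continuous, ",
      sum(x$kinds == "binary"), " binary)\n", sep = "")
  invisible(x)
}

## ---- file I/O -----------------------------------------------------------

#' Read a dataset from delimited text
#'
#' Expects a header row of unique node names. Node kinds come from a
#' two-column types file (`name<TAB>kind`), an in-memory vector, or are
#' inferred (all-\{0,1\} columns become binary). Any non-numeric or missing
#' cell is reported with its row and column.
#'
#' @param path path to a TSV/CSV file of values with a header row.
#' @param types `NULL` (infer), a named character vector, or the path of a
#'   tab-separated `name<TAB>kind` file.
#' @param sep field separator (default tab).
#' @return A [make_dataset()] object.
#' @export
read_dataset <- function(path, types = NULL, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  if (anyDuplicated(names(df))) stop("duplicate column names in ", path)
  vals <- suppressWarnings(
    vapply(df, as.numeric, numeric(nrow(df)), USE.NAMES = TRUE))
  if (nrow(df) == 1L) vals <- matrix(vals, 1, dimnames = list(NULL, names(df)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("non-numeric or missing value '", df[bad[1], bad[2]],
         "' at row ", bad[1], ", column '", names(df)[bad[2]],
         "' of ", path)
  }
  kinds <- types
  if (is.character(types) && length(types) == 1L && file.exists(types)) {
    tt <- utils::read.table(types, header = FALSE, sep = "\t",
                            col.names = c("name", "kind"),
                            stringsAsFactors = FALSE, comment.char = "#")
    kinds <- stats::setNames(tt$kind, tt$name)
  }
  make_dataset(vals, kinds)
}

#' Write a dataset as TSV with header
#' @param data a `dag_dataset`.
#' @param path output path; a companion `<path>.types` file records kinds.
#' @export
write_dataset <- function(data, path) {
  utils::write.table(data$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(name = data$nodes, kind = data$kinds),
    paste0(path, ".types"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write edge lists
#'
#' Edge-list text files are the canonical graph interchange: one edge per
#' line, tab-separated `parent<TAB>child`, `#` comments allowed, no header
#' (extra numeric columns such as edge frequencies are preserved on read,
#' ignored for graph construction). On write, edges are emitted in
#' canonical order (parent-major node order), so a read/write round trip is
#' the identity up to ordering.
#'
#' @param path file path.
#' @param nodes node set of the graph (required on read: edge lists do not
#'   mention isolated nodes).
#' @return `read_edge_list`: a `dag`; `write_edge_list`: the path.
#' @export
read_edge_list <- function(path, nodes) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) return(empty_dag(nodes))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) stop("malformed edge line in ", path)
  ## skip a header line if present
  first <- parts[[1]]
  if (identical(tolower(first[1:2]), c("parent", "child"))) parts <- parts[-1]
  edges <- do.call(rbind, lapply(parts, function(x) x[1:2]))
  dag(nodes, edges)
}

#' @rdname read_edge_list
#' @param g a `dag` to write.
#' @export
write_edge_list <- function(g, path) {
  e <- dag_edges(g)
  writeLines(paste(e$parent, e$child, sep = "\t"), path)
  invisible(path)
}

#' Read a whitelist/blacklist prior-edge file
#'
#' Two-column tab-separated `parent<TAB>child`, one edge per line, `#`
#' comments allowed.
#'
#' @param path file path.
#' @return Data frame with columns `parent`, `child`.
#' @export
read_prior_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) {
    return(data.frame(parent = character(0), child = character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) stop("malformed prior-edge line in ", path)
  data.frame(parent = vapply(parts, `[`, "", 1),
             child = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Export an adjacency matrix as CSV
#'
#' Alternative export with a header row and first column of node names.
#' @param g a `dag`.
#' @param path output path.
#' @export
write_adjacency_csv <- function(g, path) {
  M <- g$A * 1L
  utils::write.table(cbind(node = g$nodes, as.data.frame(M)), path,
                     sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, seeds, package version, input file
#' checksums and a timestamp as JSON, sufficient to replay a run.
#'
#' @param path output path.
#' @param config named list of configuration values.
#' @param seed integer seed used for the run.
#' @param inputs character vector of input file paths to checksum.
#' @export
write_run_manifest <- function(path, config, seed, inputs = character(0)) {
  sums <- vapply(inputs, function(f) as.character(tools::md5sum(f)), "")
  manifest <- list(
    package = "dagboot",
    version = as.character(utils::packageVersion("dagboot")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    input_checksums = as.list(sums)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
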