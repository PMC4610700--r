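#' Read a delay-weighted digraph from a file
#'
#' Three formats are supported:
#' \describe{
#'   \item{edgelist}{UTF-8 TSV with header `source<TAB>target<TAB>delay`,
#'     one edge per row.}
#'   \item{adjacency}{square numeric CSV; entry (row i, column j) is the
#'     delay of edge \eqn{v_i \to v_j}; 0 means no edge (legal because
#'     weights are \eqn{\ge 1}). A leading empty field in the first row
#'     marks a labeled matrix (first row/column carry vertex labels, the
#'     `write.csv` row-name convention); otherwise labels are positional
#'     `"1".."n"`.}
#'   \item{graphml}{directed GraphML with an integer edge attribute
#'     `delay` (read and written through igraph).}
#' }
#'
#' @param path file to read.
#' @param format one of `"edgelist"`, `"adjacency"`, `"graphml"`.
#' @param scale optional positive factor: when given, raw delays may be
#'   real-valued and are converted with [quantize_weights()]; when
#'   `NULL` (default) delays must already be positive integers.
#' @param tol rounding-error tolerance forwarded to [quantize_weights()].
#' @return a validated `delay_digraph`; external labels preserved,
#'   internal indices in first-appearance order (edgelist/graphml) or
#'   row order (adjacency).
#' @export
load_graph <- function(path, format = c("edgelist", "adjacency", "graphml"),
                       scale = NULL, tol = 0.1) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  ed <- switch(format,
               edgelist = read_edgelist(path),
               adjacency = read_adjacency(path),
               graphml = read_graphml(path))
  if (is.null(scale)) {
    delay_digraph(ed$edges$source, ed$edges$target, ed$edges$delay,
                  labels = ed$labels)
  } else {
    quantize_weights(ed$edges, scale = scale, tol = tol, labels = ed$labels)
  }
}

read_edgelist <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, colClasses = "character",
                      check.names = FALSE),
    error = function(e) stop("parse error in edge list ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(df) != 3)
    stop("edge list ", path, " must have 3 columns (source, target, delay), ",
         "found ", ncol(df), call. = FALSE)
  names(df) <- c("source", "target", "delay")
  df$delay <- suppressWarnings(as.numeric(df$delay))
  bad <- which(is.na(df$delay))
  if (length(bad))
    stop("parse error in edge list ", path, ": non-numeric delay on data line ",
         bad[1], call. = FALSE)
  list(edges = df, labels = NULL)
}

read_adjacency <- function(path) {
  first <- readLines(path, n = 1)
  if (!length(first))
    stop("parse error in adjacency matrix ", path, ": empty file",
         call. = FALSE)
  labeled <- startsWith(first, ",") || startsWith(first, "\"\",")
  if (labeled) {
    df <- tryCatch(
      utils::read.csv(path, header = TRUE, row.names = 1,
                      check.names = FALSE, colClasses = "character"),
      error = function(e) stop("parse error in adjacency matrix ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    labels <- rownames(df)
    if (!identical(colnames(df), labels))
      stop("adjacency matrix ", path,
           ": row labels and column labels differ", call. = FALSE)
    m <- as.matrix(df)
  } else {
    df <- tryCatch(
      utils::read.csv(path, header = FALSE, colClasses = "character"),
      error = function(e) stop("parse error in adjacency matrix ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    m <- as.matrix(df)
    labels <- as.character(seq_len(nrow(m)))
  }
  if (nrow(m) != ncol(m))
    stop("adjacency matrix ", path, " is not square: ",
         nrow(m), " rows, ", ncol(m), " columns", call. = FALSE)
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad))
    stop("parse error in adjacency matrix ", path, ": non-numeric cell (",
         bad[1, 1], ",", bad[1, 2], ")", call. = FALSE)
  hit <- which(num != 0, arr.ind = TRUE)
  edges <- data.frame(source = labels[hit[, 1]], target = labels[hit[, 2]],
                      delay = num[hit], stringsAsFactors = FALSE)
  diag_hit <- which(hit[, 1] == hit[, 2])
  if (length(diag_hit))
    stop("adjacency matrix ", path, ": self-loop at cell (",
         hit[diag_hit[1], 1], ",", hit[diag_hit[1], 2], ")", call. = FALSE)
  list(edges = edges, labels = labels)
}

read_graphml <- function(path) {
  g <- tryCatch(igraph::read_graph(path, format = "graphml"),
                error = function(e) stop("parse error in GraphML ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  if (!igraph::is_directed(g))
    stop("GraphML ", path, " is not a directed graph", call. = FALSE)
  labels <- if ("name" %in% igraph::vertex_attr_names(g))
    igraph::V(g)$name else as.character(seq_len(igraph::vcount(g)))
  if (!"delay" %in% igraph::edge_attr_names(g))
    stop("GraphML ", path, " lacks the edge attribute 'delay'",
         call. = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  list(edges = data.frame(source = labels[el[, 1]], target = labels[el[, 2]],
                          delay = as.numeric(igraph::E(g)$delay),
                          stringsAsFactors = FALSE),
       labels = labels)
}

#' Write a delay-weighted digraph to a file
#'
#' Writes in any of the formats accepted by [load_graph()] such that
#' reloading reproduces the graph (same labeled edge set, weights and
#' labels). The edge-list format cannot represent isolated vertices; a
#' warning is emitted when they would be dropped.
#'
#' @param graph a `delay_digraph`.
#' @param path destination file.
#' @param format one of `"edgelist"`, `"adjacency"`, `"graphml"`.
#' @return invisibly, `path`.
#' @export
save_graph <- function(graph, path,
                       format = c("edgelist", "adjacency", "graphml")) {
  stopifnot(inherits(graph, "delay_digraph"))
  format <- match.arg(format)
  switch(format,
    edgelist = {
      used <- sort(unique(c(graph$edges$from, graph$edges$to)))
      if (length(used) < n_vertices(graph))
        warning("edge-list format drops ", n_vertices(graph) - length(used),
                " isolated vertex/vertices", call. = FALSE)
      et <- edge_table(graph)
      names(et) <- c("source", "target", "delay")
      utils::write.table(et, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, fileEncoding = "UTF-8")
    },
    adjacency = {
      nv <- n_vertices(graph)
      m <- matrix(0L, nv, nv, dimnames = list(graph$labels, graph$labels))
      m[cbind(graph$edges$from, graph$edges$to)] <- graph$edges$w
      utils::write.csv(m, path, quote = FALSE)
    },
    graphml = {
      g <- igraph::graph_from_data_frame(edge_table(graph), directed = TRUE,
                                         vertices = graph$labels)
      igraph::E(g)$delay <- edge_table(graph)$delay
      igraph::write_graph(g, path, format = "graphml")
    })
  invisible(path)
}
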