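#' Delay-weighted directed graph
#'
#' Construct a directed graph whose edges carry positive integer
#' interaction delays. This is the central container of the package: a
#' network \eqn{G = \{V, E\}} in which every edge \eqn{(v_i, v_j)} has a
#' weight \eqn{w_{(v_i, v_j)} \ge 1} interpreted as the (scaled, integer)
#' interaction delay between the two nodes.
#'
#' Invariants enforced on construction:
#' \itemize{
#'   \item no self-loops,
#'   \item at most one edge per ordered vertex pair (antiparallel edges
#'     \eqn{(v_i, v_j)} and \eqn{(v_j, v_i)} may coexist),
#'   \item every weight is an integer \eqn{\ge 1},
#'   \item vertex labels are unique.
#' }
#'
#' Vertices are indexed internally 1..|V| in the order of `labels`; when
#' `labels` is omitted, labels are taken from the edge endpoints in
#' first-appearance order (scanning each edge row, source before target).
#'
#' @param source,target character (or coercible) vectors of edge endpoint
#'   labels, one entry per edge.
#' @param delay integer vector of positive edge delays, one per edge.
#' @param labels optional character vector of all vertex labels (allows
#'   isolated vertices and fixes the internal ordering).
#' @return An object of class `delay_digraph`: a list with components
#'   `labels` (character) and `edges` (data.frame of internal indices
#'   `from`, `to` and integer weight `w`, sorted lexicographically).
#' @examples
#' g <- delay_digraph(c("1", "2", "1"), c("2", "3", "3"), c(3, 4, 7))
#' n_edges(g)
#' graph_density(g)
#' @export
delay_digraph <- function(source, target, delay, labels = NULL) {
  source <- as.character(source)
  target <- as.character(target)
  if (length(source) != length(target) || length(source) != length(delay))
    stop("source, target and delay must have equal length", call. = FALSE)
  if (is.null(labels)) {
    labels <- unique(as.character(rbind(source, target)))
  } else {
    labels <- as.character(labels)
    if (anyDuplicated(labels))
      stop("vertex labels must be unique", call. = FALSE)
    missing <- setdiff(c(source, target), labels)
    if (length(missing))
      stop("edge endpoints not in label set: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(labels))
    stop("vertex labels must be unique", call. = FALSE)
  from <- match(source, labels)
  to   <- match(target, labels)
  bad <- which(!is.finite(delay) | delay < 1 | delay != round(delay))
  if (length(bad))
    stop("delay must be a positive integer; offending edge (",
         source[bad[1]], ", ", target[bad[1]], ") has delay ",
         delay[bad[1]], call. = FALSE)
  loop <- which(from == to)
  if (length(loop))
    stop("self-loop on vertex ", source[loop[1]], call. = FALSE)
  key <- paste(from, to)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate edge (", source[dup[1]], ", ", target[dup[1]], ")",
         call. = FALSE)
  edges <- data.frame(from = from, to = to, w = as.integer(delay))
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(labels = labels, edges = edges), class = "delay_digraph")
}

#' @export
print.delay_digraph <- function(x, ...) {
  cat(sprintf("delay_digraph: %d vertices, %d edges, density %.3f\n",
              n_vertices(x), n_edges(x),
              if (n_vertices(x) >= 2) graph_density(x) else NA_real_))
  invisible(x)
}

#' Number of vertices / edges
#' @param graph a `delay_digraph`.
#' @return integer count.
#' @export
n_vertices <- function(graph) {
  stopifnot(inherits(graph, "delay_digraph"))
  length(graph$labels)
}

#' @rdname n_vertices
#' @export
n_edges <- function(graph) {
  stopifnot(inherits(graph, "delay_digraph"))
  nrow(graph$edges)
}

#' Edge table with external labels
#'
#' @param graph a `delay_digraph`.
#' @return data.frame with character columns `source`, `target` and
#'   integer `delay`, one row per edge, in lexicographic order of the
#'   internal vertex indices.
#' @export
edge_table <- function(graph) {
  stopifnot(inherits(graph, "delay_digraph"))
  data.frame(source = graph$labels[graph$edges$from],
             target = graph$labels[graph$edges$to],
             delay = graph$edges$w,
             stringsAsFactors = FALSE)
}

#' Graph density
#'
#' The ratio of edges present to the number of possible directed edges,
#' \eqn{\rho = |E| / (|V| (|V| - 1))}.
#'
#' @param graph a `delay_digraph` with at least 2 vertices.
#' @return density in \[0, 1\].
#' @export
graph_density <- function(graph) {
  stopifnot(inherits(graph, "delay_digraph"))
  nv <- n_vertices(graph)
  if (nv < 2) stop("density requires at least 2 vertices", call. = FALSE)
  n_edges(graph) / (nv * (nv - 1))
}

#' Test two graphs for equality
#'
#' Equal means: the same vertex label set, the same labeled edge set and
#' the same weights. Internal index order is irrelevant.
#'
#' @param a,b `delay_digraph` objects.
#' @return logical.
#' @export
graph_identical <- function(a, b) {
  stopifnot(inherits(a, "delay_digraph"), inherits(b, "delay_digraph"))
  if (!setequal(a$labels, b$labels)) return(FALSE)
  ea <- edge_table(a); eb <- edge_table(b)
  if (nrow(ea) != nrow(eb)) return(FALSE)
  ka <- paste(ea$source, ea$target, ea$delay, sep = "\r")
  kb <- paste(eb$source, eb$target, eb$delay, sep = "\r")
  setequal(ka, kb)
}

# internal: index of an edge given endpoint labels; NA if absent
edge_index <- function(graph, source, target) {
  s <- match(as.character(source), graph$labels)
  t <- match(as.character(target), graph$labels)
  if (is.na(s) || is.na(t)) return(NA_integer_)
  hit <- which(graph$edges$from == s & graph$edges$to == t)
  if (length(hit)) hit[1] else NA_integer_
}

#' Quantize real-valued delays to integer weights
#'
#' The path-search algorithm indexes its memoization table by integer
#' weight, so real-valued delays (e.g. milliseconds with decimals) must
#' be linearly scaled to integers first: each weight becomes
#' `round(delay * scale)`.
#'
#' @param edges data.frame with columns `source`, `target` and numeric
#'   positive `delay`.
#' @param scale positive scaling factor applied before rounding.
#' @param tol maximum tolerated relative rounding error per edge before
#'   a warning is emitted (default 0.1, i.e. 10\%).
#' @param labels optional vertex label vector passed to [delay_digraph()].
#' @return a `delay_digraph` with integer weights.
#' @examples
#' quantize_weights(data.frame(source = "a", target = "b", delay = 6.8),
#'                  scale = 10)
#' @export
quantize_weights <- function(edges, scale = 1, tol = 0.1, labels = NULL) {
  if (!is.data.frame(edges) ||
      !all(c("source", "target", "delay") %in% names(edges)))
    stop("edges must be a data.frame with source, target, delay",
         call. = FALSE)
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0)
    stop("scale must be a positive number", call. = FALSE)
  if (any(!is.finite(edges$delay) | edges$delay <= 0))
    stop("all raw delays must be positive", call. = FALSE)
  w <- round(edges$delay * scale)
  zero <- which(w == 0)
  if (length(zero))
    stop("delay ", edges$delay[zero[1]], " on edge (",
         edges$source[zero[1]], ", ", edges$target[zero[1]],
         ") rounds to 0 at scale ", scale,
         "; use a larger scale factor", call. = FALSE)
  rel <- abs(w - edges$delay * scale) / (edges$delay * scale)
  if (any(rel > tol))
    warning(sum(rel > tol), " edge weight(s) incur relative rounding ",
            "error above ", tol, "; consider a larger scale factor",
            call. = FALSE)
  delay_digraph(edges$source, edges$target, w, labels = labels)
}
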