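# Brute-force reference implementations, kept deliberately independent of
# the memoized search (no shared traversal code) so they can serve as
# oracles in tests, plus the estimation-cost and network-overlap
# calculators.

#' Enumerate all simple paths in a weight interval (brute force)
#'
#' Exhaustive depth-first enumeration of every simple path from `s` to
#' `t`, optionally avoiding one edge, returning exactly those whose
#' summed weight lies in `[w_lo, w_hi]`. Exponential in the worst case;
#' intended as a verification oracle for small graphs only.
#'
#' @param graph a `delay_digraph`.
#' @param s,t source and target vertex labels (`s != t`).
#' @param w_lo,w_hi inclusive weight interval, `0 <= w_lo <= w_hi`.
#' @param exclude_edge optional length-2 label vector; paths may not use
#'   this edge.
#' @param max_vertices guard against factorial blow-up: graphs larger
#'   than this are refused (default 12).
#' @return list of paths, each a list with `vertices` (labels),
#'   `total_weight`, `graphical_length`; ordered by weight then
#'   lexicographically by vertex sequence.
#' @export
enumerate_simple_paths <- function(graph, s, t, w_lo, w_hi,
                                   exclude_edge = NULL, max_vertices = 12) {
  stopifnot(inherits(graph, "delay_digraph"))
  if (n_vertices(graph) > max_vertices)
    stop("graph exceeds the oracle cap of ", max_vertices, " vertices",
         call. = FALSE)
  si <- match(as.character(s), graph$labels)
  ti <- match(as.character(t), graph$labels)
  if (is.na(si) || is.na(ti)) stop("unknown vertex label", call. = FALSE)
  if (si == ti) stop("s and t must differ", call. = FALSE)
  if (w_lo < 0 || w_lo > w_hi) stop("need 0 <= w_lo <= w_hi", call. = FALSE)
  ed <- graph$edges
  if (!is.null(exclude_edge)) {
    xi <- edge_index(graph, exclude_edge[1], exclude_edge[2])
    if (!is.na(xi)) ed <- ed[-xi, , drop = FALSE]
  }
  succ <- split(seq_len(nrow(ed)), ed$from)
  found <- list()
  walk <- function(v, wsum, path) {
    for (id in succ[[as.character(v)]]) {
      nxt <- ed$to[id]
      nw <- wsum + ed$w[id]
      if (nw > w_hi || nxt %in% path) next
      if (nxt == ti) {
        if (nw >= w_lo)
          found[[length(found) + 1L]] <<- list(idx = c(path, nxt), w = nw)
      } else {
        walk(nxt, nw, c(path, nxt))
      }
    }
  }
  walk(si, 0L, si)
  paths <- lapply(found, function(f)
    list(vertices = graph$labels[f$idx], total_weight = f$w,
         graphical_length = length(f$idx) - 1L))
  key <- vapply(paths, function(p)
    sprintf("%09d|%s", p$total_weight, paste(p$vertices, collapse = ",")),
    character(1))
  paths[order(key)]
}

#' Does a walk of an exact total weight exist? (brute force)
#'
#' Forward reachability over (vertex, accumulated weight) states: returns
#' `TRUE` iff a walk (vertex repeats allowed) from `s` to `v` with summed
#' weight exactly `exact_weight` exists, optionally avoiding one edge.
#' Walks re-entering the start vertex are not considered — consistent
#' with the solution-array semantics, where such walks are never
#' represented because they cannot extend to simple alternative paths.
#'
#' @param graph a `delay_digraph`.
#' @param s,v start and end vertex labels.
#' @param exact_weight required total walk weight (>= 0; 0 means the
#'   empty walk, which exists iff `v == s`).
#' @param exclude_edge optional length-2 label vector of an edge to avoid.
#' @return logical.
#' @export
walk_exists <- function(graph, s, v, exact_weight, exclude_edge = NULL) {
  stopifnot(inherits(graph, "delay_digraph"))
  si <- match(as.character(s), graph$labels)
  vi <- match(as.character(v), graph$labels)
  if (is.na(si) || is.na(vi)) stop("unknown vertex label", call. = FALSE)
  if (!is.numeric(exact_weight) || exact_weight < 0 ||
      exact_weight != round(exact_weight))
    stop("exact_weight must be a non-negative integer", call. = FALSE)
  W <- as.integer(exact_weight)
  if (W == 0L) return(vi == si)
  ed <- graph$edges
  if (!is.null(exclude_edge)) {
    xi <- edge_index(graph, exclude_edge[1], exclude_edge[2])
    if (!is.na(xi)) ed <- ed[-xi, , drop = FALSE]
  }
  ed <- ed[ed$to != si, , drop = FALSE]      # never re-enter the start
  n <- n_vertices(graph)
  reach <- matrix(FALSE, W + 1L, n)          # row r+1: weight r
  reach[1L, si] <- TRUE
  for (r in seq_len(W)) {
    src_row <- r - ed$w + 1L
    ok <- src_row >= 1L
    ok[ok] <- reach[cbind(src_row[ok], ed$from[ok])]
    if (any(ok)) reach[r + 1L, unique(ed$to[ok])] <- TRUE
  }
  reach[W + 1L, vi]
}

#' Largest network size at which two-stage estimation is not yet cheaper
#'
#' Cost model for obtaining order-3 multivariate interaction estimates:
#' the two-stage approach performs `|V|(|V|-1)` bivariate estimations
#' plus 6 targeted trivariate estimations per triangle motif actually
#' present (a fraction `f` of the `choose(|V|, 3)` possible motifs); the
#' brute-force approach performs all `6 * choose(|V|, 3)` trivariate
#' estimations. Returns the largest `|V|` at which the two-stage cost is
#' still >= the brute-force cost; for all larger networks the two-stage
#' approach is strictly cheaper. At the motif fraction `f = 0.9` the
#' crossover is `|V| = 12`.
#'
#' @param f fraction of possible triangle motifs present, `0 <= f < 1`.
#' @return integer network size.
#' @export
crossover_size <- function(f) {
  if (!is.numeric(f) || length(f) != 1 || f < 0)
    stop("f must be a fraction in [0, 1)", call. = FALSE)
  if (f >= 1)
    stop("f must be < 1: with every motif present the two-stage ",
         "approach is never cheaper", call. = FALSE)
  two_stage <- function(v) v * (v - 1) + 6 * f * choose(v, 3)
  brute <- function(v) 6 * choose(v, 3)
  v <- max(3L, as.integer(floor(2 + 1 / (1 - f) + 1e-9)))
  while (two_stage(v + 1L) >= brute(v + 1L)) v <- v + 1L
  while (v > 3L && two_stage(v) < brute(v)) v <- v - 1L
  v
}

#' Overlap statistics between two edge sets
#'
#' Summary of how consistent two networks over the same vertex set are:
#' the shared edge count, the overlap as a percentage of the smaller
#' edge set, and the overlap expected purely by chance — the probability
#' (in percent) that a given directed edge lies in both sets if each set
#' were placed uniformly at random among the `P = |V|(|V|-1)` possible
#' edges, i.e. `100 * (|A|/P) * (|B|/P)`.
#'
#' @param edges_a,edges_b data.frames with character columns `source`
#'   and `target` (or `delay_digraph`s, whose edge tables are used);
#'   both non-empty.
#' @param n_vertices size of the common vertex set (>= 2).
#' @return list with `shared_count`, `pct_of_smaller`, `chance_pct`.
#' @examples
#' a <- data.frame(source = as.character(1:20), target = as.character(2:21))
#' # 20- and 34-edge networks over 14 nodes sharing 9 edges give a 45%
#' # overlap against about 2% expected by chance; see overlap_stats().
#' @export
overlap_stats <- function(edges_a, edges_b, n_vertices) {
  as_keys <- function(x) {
    if (inherits(x, "delay_digraph")) x <- edge_table(x)
    if (!is.data.frame(x) || !all(c("source", "target") %in% names(x)))
      stop("edge sets must be data.frames with source and target columns",
           call. = FALSE)
    unique(paste(x$source, x$target, sep = "\r"))
  }
  ka <- as_keys(edges_a); kb <- as_keys(edges_b)
  if (!length(ka) || !length(kb))
    stop("overlap is undefined for an empty edge set", call. = FALSE)
  if (!is.numeric(n_vertices) || n_vertices < 2)
    stop("n_vertices must be >= 2", call. = FALSE)
  P <- n_vertices * (n_vertices - 1)
  shared <- length(intersect(ka, kb))
  list(shared_count = shared,
       pct_of_smaller = 100 * shared / min(length(ka), length(kb)),
       chance_pct = 100 * (length(ka) / P) * (length(kb) / P))
}
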