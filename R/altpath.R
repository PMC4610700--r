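#' Preprocess one edge into a path-search problem instance
#'
#' For an examined edge \eqn{(v_a, v_b)} the search for alternative paths
#' operates on the reduced graph \eqn{G' = G \setminus (v_a, v_b)} with the
#' vertices relabeled so that the start vertex \eqn{v_s = v_a} has internal
#' index 1 and the target \eqn{v_t = v_b} has index |V|. The critical
#' weight — the largest path weight the memoization explores — is
#' \eqn{w_{crit} = w_{(v_a, v_b)} + \theta}.
#'
#' @param graph a `delay_digraph`.
#' @param edge length-2 vector of vertex labels `c(source, target)`; the
#'   edge must exist in `graph`.
#' @param theta non-negative integer delay tolerance.
#' @return an object of class `problem_instance`: list with the reduced
#'   edge set in new indexing (`edges`), the inverted adjacency list
#'   (`pred`, per-vertex predecessor/weight matrices), `n`, `w_edge`,
#'   `theta`, `w_crit`, the label vector in new order (`labels`) and the
#'   examined edge's labels (`edge`).
#' @export
preprocess_edge <- function(graph, edge, theta) {
  stopifnot(inherits(graph, "delay_digraph"))
  if (length(edge) != 2)
    stop("edge must be c(source, target)", call. = FALSE)
  if (!is.numeric(theta) || length(theta) != 1 || theta < 0 ||
      theta != round(theta))
    stop("theta must be a non-negative integer", call. = FALSE)
  ei <- edge_index(graph, edge[1], edge[2])
  if (is.na(ei))
    stop("edge (", edge[1], ", ", edge[2], ") not in graph", call. = FALSE)
  n <- n_vertices(graph)
  a <- graph$edges$from[ei]
  b <- graph$edges$to[ei]
  w_edge <- graph$edges$w[ei]
  # new index: v_s -> 1, v_t -> n, remaining vertices keep relative order
  rest <- setdiff(seq_len(n), c(a, b))
  new_of_old <- integer(n)
  new_of_old[a] <- 1L
  new_of_old[b] <- n
  new_of_old[rest] <- seq_along(rest) + 1L
  ed <- graph$edges[-ei, , drop = FALSE]
  edges <- data.frame(from = new_of_old[ed$from], to = new_of_old[ed$to],
                      w = ed$w)
  edges <- edges[order(edges$to, edges$from), , drop = FALSE]
  rownames(edges) <- NULL
  pred <- lapply(seq_len(n), function(j) {
    sel <- edges$to == j
    cbind(p = edges$from[sel], w = edges$w[sel])
  })
  labels_new <- character(n)
  labels_new[new_of_old] <- graph$labels
  structure(list(edges = edges, pred = pred, n = n,
                 w_edge = w_edge, theta = as.integer(theta),
                 w_crit = w_edge + as.integer(theta),
                 labels = labels_new,
                 edge = c(graph$labels[a], graph$labels[b])),
            class = "problem_instance")
}

#' Fill the solution array by memoized dynamic programming
#'
#' Solves, for every path weight \eqn{w_i = 1..w_{crit}} (outer loop) and
#' every vertex \eqn{v_j} (inner loop), the subproblem "does a walk from
#' \eqn{v_s} to \eqn{v_j} of total weight exactly \eqn{w_i} exist in
#' \eqn{G'}?". A solution cell \eqn{L(w_i, v_j)} collects tuples
#' \eqn{(w_{(v_p, v_j)}, v_p)} — one per incoming edge \eqn{(v_p, v_j)}
#' whose predecessor cell \eqn{L(w_i - w_{(v_p,v_j)}, v_p)} is non-empty.
#' The base cell is \eqn{L(0, v_s) = \{(0, v_s)\}}; the start column stays
#' empty for \eqn{w_i > 0} (a walk re-entering the start can never extend
#' to a simple alternative path). The treatment of one incoming edge is
#' one algorithmic step, so exactly
#' \eqn{w_{crit} \cdot |E(G')|} steps are executed.
#'
#' @param instance a `problem_instance` from [preprocess_edge()].
#' @return an object of class `solution_array`: list with `nonempty`
#'   (logical matrix, rows = weights 0..w_crit, columns = vertices),
#'   `row_edges` (per weight row, the indices into `instance$edges` whose
#'   tuple was entered), and the step counter `steps`.
#' @export
solve_subproblems <- function(instance) {
  stopifnot(inherits(instance, "problem_instance"))
  n <- instance$n
  wc <- instance$w_crit
  ef <- instance$edges$from
  et <- instance$edges$to
  ew <- instance$edges$w
  ne <- matrix(FALSE, nrow = wc + 1L, ncol = n)
  ne[1L, 1L] <- TRUE
  row_edges <- vector("list", wc + 1L)
  row_edges[[1L]] <- integer(0)
  if (length(ef)) {
    for (wi in seq_len(wc)) {
      prev <- wi - ew + 1L            # 1-based row of the required cell
      ok <- prev >= 1L & et != 1L
      ok[ok] <- ne[cbind(prev[ok], ef[ok])]
      valid <- which(ok)
      row_edges[[wi + 1L]] <- valid
      if (length(valid)) ne[wi + 1L, unique(et[valid])] <- TRUE
    }
  } else {
    for (wi in seq_len(wc)) row_edges[[wi + 1L]] <- integer(0)
  }
  structure(list(nonempty = ne, row_edges = row_edges,
                 steps = wc * length(ef)),
            class = "solution_array")
}

# internal: tuples (edge weight, predecessor) of cell (w_row, vertex v),
# ordered by ascending predecessor index; `cache` (an environment) memoizes
# the per-row split by target vertex for repeated lookups
cell_tuples <- function(array, instance, w_row, v, cache = NULL) {
  if (is.null(cache)) {
    ids <- array$row_edges[[w_row + 1L]]
    ids <- ids[instance$edges$to[ids] == v]
    return(ids[order(instance$edges$from[ids])])
  }
  key <- as.character(w_row)
  byt <- cache[[key]]
  if (is.null(byt)) {
    ids <- array$row_edges[[w_row + 1L]]
    ids <- ids[order(instance$edges$to[ids], instance$edges$from[ids])]
    byt <- split(ids, instance$edges$to[ids])
    cache[[key]] <- byt
  }
  byt[[as.character(v)]]
}

#' Reconstruct alternative paths by depth-first backtracking
#'
#' Starting from every non-empty solution cell \eqn{(w, v_t)} with `w` in
#' the reconstruction interval \eqn{[w_{(v_a,v_b)} - \theta,
#' w_{(v_a,v_b)} + \theta]} (clamped below at 0), the solution array is
#' expanded depth-first towards the start vertex. Expansions that revisit
#' a vertex already on the partial path contain a loop and are discarded;
#' the remaining vertex sequences are simple alternative paths. When the
#' number of valid reconstructed paths reaches `limit`, reconstruction
#' stops and the result is flagged intractable.
#'
#' @param array a `solution_array` produced from `instance`.
#' @param instance the matching `problem_instance`.
#' @param limit positive integer cap on reconstructed paths
#'   (default 20000).
#' @return an object of class `alt_path_result`: the examined edge and
#'   its weight, `theta`, the list of paths (each with `vertices` as
#'   external labels, `total_weight`, `graphical_length`),
#'   `has_alternative`, `intractable`, and counters `dp_steps`,
#'   `n_paths`, `n_loop_discards`.
#' @export
backtrack_paths <- function(array, instance, limit = 20000) {
  stopifnot(inherits(array, "solution_array"),
            inherits(instance, "problem_instance"))
  if (!is.numeric(limit) || length(limit) != 1 || limit < 1 ||
      limit != round(limit))
    stop("limit must be a positive integer", call. = FALSE)
  n <- instance$n
  lo <- max(0L, instance$w_edge - instance$theta)
  hi <- instance$w_crit
  state <- new.env(parent = emptyenv())
  state$paths <- vector("list", 256L)
  state$count <- 0L
  state$discard <- 0L
  state$hit_limit <- FALSE
  cache <- new.env(parent = emptyenv())
  edge_from <- instance$edges$from
  edge_w <- instance$edges$w

  expand <- function(v, w_row, suffix) {
    # suffix: vertices from v to v_t (new indexing), v included
    for (id in cell_tuples(array, instance, w_row, v, cache)) {
      if (state$hit_limit) return(invisible())
      p <- edge_from[id]
      if (p == 1L) {                      # reached v_s; w_row - w is 0
        state$count <- state$count + 1L
        if (state$count > length(state$paths))
          length(state$paths) <- 2L * length(state$paths)
        state$paths[[state$count]] <- c(1L, suffix)
        if (state$count >= limit) state$hit_limit <- TRUE
      } else if (p %in% suffix) {
        state$discard <- state$discard + 1L
      } else {
        expand(p, w_row - edge_w[id], c(p, suffix))
      }
    }
    invisible()
  }

  weights <- integer(0)
  for (w in lo:hi) {
    if (array$nonempty[w + 1L, n]) {
      before <- state$count
      expand(n, w, n)
      weights <- c(weights, rep.int(w, state$count - before))
      if (state$hit_limit) break
    }
  }
  paths <- if (state$count) state$paths[seq_len(state$count)] else list()
  paths <- Map(function(idx, tw) {
    list(vertices = instance$labels[idx],
         total_weight = tw,
         graphical_length = length(idx) - 1L)
  }, paths, as.list(weights))
  structure(list(edge = instance$edge, w_edge = instance$w_edge,
                 theta = instance$theta, w_crit = instance$w_crit,
                 paths = paths,
                 has_alternative = state$count > 0L || state$hit_limit,
                 intractable = state$hit_limit,
                 dp_steps = array$steps,
                 n_paths = state$count,
                 n_loop_discards = state$discard),
            class = "alt_path_result")
}

#' Find all alternative paths for one edge
#'
#' Composition of [preprocess_edge()], [solve_subproblems()] and
#' [backtrack_paths()]: returns every simple path from the edge's source
#' to its target that avoids the edge itself and whose summed delay lies
#' within \eqn{\theta} of the edge's delay. An edge with at least one
#' such path is a potential cascade effect.
#'
#' @inheritParams preprocess_edge
#' @inheritParams backtrack_paths
#' @return an `alt_path_result`; see [backtrack_paths()].
#' @examples
#' g <- delay_digraph(c("1", "2", "1"), c("2", "3", "3"), c(3, 4, 7))
#' res <- find_alternative_paths(g, c("1", "3"), theta = 0)
#' res$paths[[1]]$vertices
#' @export
find_alternative_paths <- function(graph, edge, theta, limit = 20000) {
  inst <- preprocess_edge(graph, edge, theta)
  backtrack_paths(solve_subproblems(inst), inst, limit = limit)
}

#' @export
print.alt_path_result <- function(x, ...) {
  cat(sprintf("edge (%s, %s) w=%d theta=%d: %d alternative path(s)%s\n",
              x$edge[1], x$edge[2], x$w_edge, x$theta, x$n_paths,
              if (x$intractable) " [intractable: limit hit]" else ""))
  invisible(x)
}
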