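#' Tag cascade-effect candidates over a whole network
#'
#' Runs the alternative-path search for every edge of the graph, each
#' time against the full original graph minus only the examined edge
#' (never against a partially pruned graph, so results are independent
#' of edge order). Edges with at least one alternative path — or whose
#' path reconstruction hit the limit — are tagged as potential cascade
#' effects (CE).
#'
#' @param graph a `delay_digraph`.
#' @param theta non-negative integer delay tolerance.
#' @param limit positive integer path-reconstruction cap per edge
#'   (default 20000).
#' @param on_limit `"mark"` (default) flags the edge as intractable and
#'   continues; `"abort"` stops the whole run with an error of class
#'   `spurnet_limit_abort`.
#' @return an object of class `tagging_result`: the graph, `theta`,
#'   `limit`, per-edge `alt_path_result`s (`results`, in lexicographic
#'   edge order), the CE edge table (`ce_edges`), placeholders for CD
#'   tags/triangles (filled by [tag_common_drive()]), the intractable
#'   edge table and the total DP step count.
#' @export
tag_cascade_effects <- function(graph, theta, limit = 20000,
                                on_limit = c("mark", "abort")) {
  stopifnot(inherits(graph, "delay_digraph"))
  on_limit <- match.arg(on_limit)
  et <- edge_table(graph)
  results <- vector("list", nrow(et))
  for (i in seq_len(nrow(et))) {
    res <- find_alternative_paths(graph, c(et$source[i], et$target[i]),
                                  theta, limit = limit)
    if (res$intractable && on_limit == "abort")
      stop(structure(class = c("spurnet_limit_abort", "error", "condition"),
                     list(message = paste0("path-reconstruction limit ",
                                           limit, " reached for edge (",
                                           et$source[i], ", ", et$target[i],
                                           ")"),
                          call = sys.call())))
    results[[i]] <- res
  }
  ce <- vapply(results, function(r) r$has_alternative, logical(1))
  intract <- vapply(results, function(r) r$intractable, logical(1))
  structure(list(graph = graph, theta = as.integer(theta),
                 limit = as.integer(limit),
                 results = results,
                 ce_edges = et[ce, , drop = FALSE],
                 cd_edges = et[0, , drop = FALSE],
                 triangles = NULL,
                 intractable_edges = et[intract, , drop = FALSE],
                 total_dp_steps = sum(vapply(results, function(r)
                   as.numeric(r$dp_steps), numeric(1)))),
            class = "tagging_result")
}

#' Add simple common-drive tags from triangle motifs
#'
#' Every alternative path of graphical length exactly 2 of a CE-tagged
#' edge \eqn{(v_s, v_t)}, say \eqn{\langle v_s, v_1, v_t\rangle},
#' identifies a triangle motif in which the second edge \eqn{(v_1, v_t)}
#' may instead be the result of a simple common drive (both \eqn{v_1}
#' and \eqn{v_t} driven by \eqn{v_s} with differential delays). One CD
#' tag is recorded per distinct triangle. At most one of the two tagged
#' edges of a triangle can actually be spurious; the tool reports both
#' and leaves the decision to the prune policy.
#'
#' @param result a `tagging_result` from [tag_cascade_effects()].
#' @return the `tagging_result` with `cd_edges` and `triangles` filled;
#'   `triangles` has one row per distinct motif with columns `v_s`,
#'   `v_1`, `v_t`, the three delays and the CD-tagged edge.
#' @export
tag_common_drive <- function(result) {
  stopifnot(inherits(result, "tagging_result"))
  tri <- list()
  for (r in result$results) {
    if (!r$has_alternative) next
    for (p in r$paths) {
      if (p$graphical_length != 2L) next
      tri[[length(tri) + 1L]] <- data.frame(
        v_s = r$edge[1], v_1 = p$vertices[2], v_t = r$edge[2],
        w_s1 = edge_weight(result$graph, p$vertices[1], p$vertices[2]),
        w_1t = edge_weight(result$graph, p$vertices[2], p$vertices[3]),
        w_st = r$w_edge,
        cd_source = p$vertices[2], cd_target = p$vertices[3],
        stringsAsFactors = FALSE)
    }
  }
  if (length(tri)) {
    triangles <- do.call(rbind, tri)
    triangles <- triangles[!duplicated(triangles[c("v_s", "v_1", "v_t")]), ,
                           drop = FALSE]
    rownames(triangles) <- NULL
    cd_key <- unique(paste(triangles$cd_source, triangles$cd_target,
                           sep = "\r"))
    et <- edge_table(result$graph)
    result$cd_edges <- et[paste(et$source, et$target, sep = "\r") %in% cd_key,
                          , drop = FALSE]
    result$triangles <- triangles
  } else {
    result$triangles <- data.frame(v_s = character(0), v_1 = character(0),
                                   v_t = character(0), w_s1 = integer(0),
                                   w_1t = integer(0), w_st = integer(0),
                                   cd_source = character(0),
                                   cd_target = character(0),
                                   stringsAsFactors = FALSE)
  }
  result
}

# internal: weight of edge (source, target), NA if absent
edge_weight <- function(graph, source, target) {
  ei <- edge_index(graph, source, target)
  if (is.na(ei)) NA_integer_ else graph$edges$w[ei]
}

#' Run the full spurious-edge tagging pipeline
#'
#' Convenience wrapper: [tag_cascade_effects()] followed by
#' [tag_common_drive()].
#'
#' @inheritParams tag_cascade_effects
#' @return a complete `tagging_result`.
#' @examples
#' g <- delay_digraph(c("1", "2", "1"), c("2", "3", "3"), c(3, 4, 7))
#' res <- tag_spurious_edges(g, theta = 0)
#' tags_table(res)
#' @export
tag_spurious_edges <- function(graph, theta, limit = 20000,
                               on_limit = c("mark", "abort")) {
  tag_common_drive(tag_cascade_effects(graph, theta, limit = limit,
                                       on_limit = on_limit))
}

#' Per-edge tag summary
#'
#' @param result a `tagging_result`.
#' @return data.frame with one row per tagged edge: `source`, `target`,
#'   `delay`, `tag` (`"CE"`, `"CD"` or `"CE+CD"`), `n_alt_paths`,
#'   `intractable`.
#' @export
tags_table <- function(result) {
  stopifnot(inherits(result, "tagging_result"))
  et <- edge_table(result$graph)
  key <- paste(et$source, et$target, sep = "\r")
  ce_key <- paste(result$ce_edges$source, result$ce_edges$target, sep = "\r")
  cd_key <- paste(result$cd_edges$source, result$cd_edges$target, sep = "\r")
  is_ce <- key %in% ce_key
  is_cd <- key %in% cd_key
  keep <- is_ce | is_cd
  tag <- ifelse(is_ce & is_cd, "CE+CD", ifelse(is_ce, "CE", "CD"))
  n_alt <- vapply(result$results, function(r) r$n_paths, integer(1))
  intract <- vapply(result$results, function(r) r$intractable, logical(1))
  out <- data.frame(source = et$source, target = et$target,
                    delay = et$delay, tag = tag,
                    n_alt_paths = n_alt, intractable = intract,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Prune tagged edges from a graph
#'
#' @param graph the graph the tagging was computed on.
#' @param result the matching `tagging_result`.
#' @param policy which tags to remove: `"all"` (CE and CD), `"ce-only"`,
#'   `"cd-only"`, or `"report-only"` (remove nothing).
#' @return a `delay_digraph` copy with the selected edges removed. The
#'   removal log — each removed edge with its tag kinds — is attached as
#'   attribute `"removed"`; when `policy = "all"` removes both edges of
#'   a triangle motif (mutually exclusive candidates, at most one can
#'   truly be spurious) the affected triangles are attached as attribute
#'   `"mutually_exclusive"`.
#' @export
prune_graph <- function(graph, result,
                        policy = c("all", "ce-only", "cd-only",
                                   "report-only")) {
  stopifnot(inherits(graph, "delay_digraph"),
            inherits(result, "tagging_result"))
  policy <- match.arg(policy)
  if (!graph_identical(graph, result$graph))
    stop("tagging result was computed on a different graph", call. = FALSE)
  tags <- tags_table(result)
  remove <- switch(policy,
                   "all" = tags,
                   "ce-only" = tags[grepl("CE", tags$tag), , drop = FALSE],
                   "cd-only" = tags[grepl("CD", tags$tag), , drop = FALSE],
                   "report-only" = tags[0, , drop = FALSE])
  et <- edge_table(graph)
  key <- paste(et$source, et$target, sep = "\r")
  drop_key <- paste(remove$source, remove$target, sep = "\r")
  keep <- !(key %in% drop_key)
  out <- delay_digraph(et$source[keep], et$target[keep], et$delay[keep],
                       labels = graph$labels)
  attr(out, "removed") <- remove
  if (policy == "all" && !is.null(result$triangles) &&
      nrow(result$triangles)) {
    tri <- result$triangles
    both <- paste(tri$v_s, tri$v_t, sep = "\r") %in% drop_key &
      paste(tri$cd_source, tri$cd_target, sep = "\r") %in% drop_key
    attr(out, "mutually_exclusive") <- tri[both, , drop = FALSE]
  }
  out
}

#' @export
print.tagging_result <- function(x, ...) {
  tt <- tags_table(x)
  cat(sprintf(paste0("tagging_result: |V|=%d |E|=%d theta=%d: %d CE edge(s),",
                     " %d CD edge(s), %d intractable\n"),
              n_vertices(x$graph), n_edges(x$graph), x$theta,
              nrow(x$ce_edges), nrow(x$cd_edges),
              nrow(x$intractable_edges)))
  if (nrow(tt)) print(tt)
  invisible(x)
}
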