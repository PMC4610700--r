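#' Write the per-edge tag table as TSV
#'
#' Columns: `source`, `target`, `delay`, `tag` (`CE`, `CD` or `CE+CD`),
#' `n_alt_paths`, `intractable`.
#'
#' @param result a `tagging_result`.
#' @param path destination file.
#' @return invisibly, `path`.
#' @export
write_tags_tsv <- function(result, path) {
  utils::write.table(tags_table(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tag table written by [write_tags_tsv()]
#'
#' @param path file to read.
#' @return data.frame with the tag columns.
#' @export
read_tags_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE,
                          colClasses = c("character", "character", "numeric",
                                         "character", "numeric", "logical"))
  if (!all(c("source", "target", "delay", "tag") %in% names(df)))
    stop("not a tag table: ", path, call. = FALSE)
  df
}

#' Dump all alternative paths as TSV
#'
#' Columns: `source`, `target`, `path` (comma-joined vertex labels),
#' `total_weight`.
#'
#' @param result a `tagging_result` or a single `alt_path_result`.
#' @param path destination file.
#' @return invisibly, `path`.
#' @export
write_paths_tsv <- function(result, path) {
  results <- if (inherits(result, "alt_path_result")) list(result)
             else if (inherits(result, "tagging_result")) result$results
             else stop("result must be a tagging_result or alt_path_result",
                       call. = FALSE)
  rows <- list()
  for (r in results) {
    for (p in r$paths) {
      rows[[length(rows) + 1L]] <- data.frame(
        source = r$edge[1], target = r$edge[2],
        path = paste(p$vertices, collapse = ","),
        total_weight = p$total_weight, stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(source = character(0), target = character(0),
                        path = character(0), total_weight = integer(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the JSON run report
#'
#' Machine-readable summary of a tagging run: a provenance header
#' (package version, parameters, optional seed), graph summary (|V|,
#' |E|, density), per-tag counts, the triangle list, intractable edges,
#' total step counts and, when a pruned graph is supplied, the removed
#' edges.
#'
#' @param result a `tagging_result`.
#' @param path destination file.
#' @param pruned optional pruned `delay_digraph` from [prune_graph()]
#'   whose removal log should be included.
#' @param seed optional seed to echo into the provenance header.
#' @return invisibly, `path`.
#' @export
write_report_json <- function(result, path, pruned = NULL, seed = NULL) {
  stopifnot(inherits(result, "tagging_result"))
  g <- result$graph
  tags <- tags_table(result)
  report <- list(
    provenance = list(
      tool = "spurnet",
      version = as.character(utils::packageVersion("spurnet")),
      theta = result$theta,
      path_limit = result$limit,
      seed = seed),
    graph = list(n_vertices = n_vertices(g), n_edges = n_edges(g),
                 density = if (n_vertices(g) >= 2) graph_density(g)
                           else NULL),
    tag_counts = list(ce = nrow(result$ce_edges),
                      cd = nrow(result$cd_edges),
                      tagged_edges = nrow(tags),
                      intractable = nrow(result$intractable_edges)),
    triangles = result$triangles,
    intractable_edges = result$intractable_edges,
    total_dp_steps = result$total_dp_steps,
    total_paths = sum(vapply(result$results,
                             function(r) as.numeric(r$n_paths), numeric(1))))
  if (!is.null(pruned)) {
    report$pruned_edges <- attr(pruned, "removed")
    me <- attr(pruned, "mutually_exclusive")
    if (!is.null(me) && nrow(me)) report$mutually_exclusive_triangles <- me
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
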