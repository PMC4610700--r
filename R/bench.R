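#' Hardware-independent benchmark harness
#'
#' Reruns the tagging pipeline over a parameter grid of network models,
#' sizes and critical path weights, recording step counters instead of
#' wall-clock time: the memoized search executes exactly
#' `w_crit * |E(G')|` algorithmic steps per examined edge, so the
#' counters expose the linear scaling of the dynamic program and the
#' (potentially exponential) growth of the reconstructed path count
#' without any hardware dependence.
#'
#' The grid's `w_crit` is imposed by giving each examined edge the
#' per-edge tolerance `theta_e = max(0, w_crit - w_e)`, so every edge's
#' search explores path weights up to (at least) the grid value.
#'
#' @param models list of model specifications; each a named list with
#'   `model` (`"random"`, `"smallworld"` or `"scalefree"`) plus its
#'   parameters (`rho`; `neighbors` and `p_rewire`; or `m`). An optional
#'   `label` overrides the auto-generated model label.
#' @param sizes integer vector of network sizes `|V|`.
#' @param w_crit_values integer vector of critical path weights.
#' @param seeds integer vector of generator seeds.
#' @param w_max maximum edge weight for all generators (default 17).
#' @param limit path-reconstruction cap per edge (default 20000);
#'   reaching it marks the edge intractable.
#' @param max_edges optional cap on the number of edges examined per
#'   network (first `max_edges` in lexicographic order); `Inf` examines
#'   all.
#' @return data.frame with one row per grid cell: `model`, `n_nodes`,
#'   `w_crit`, `seed`, `n_edges`, `n_examined`, `dp_steps` (summed over
#'   examined edges), `n_paths` (valid reconstructed paths, summed),
#'   `n_intractable`.
#' @export
bench_grid <- function(models, sizes, w_crit_values, seeds, w_max = 17,
                       limit = 20000, max_edges = Inf) {
  if (!is.list(models))
    stop("models must be a list of model specifications", call. = FALSE)
  if (!length(models) || !length(sizes) || !length(w_crit_values) ||
      !length(seeds))
    return(data.frame(model = character(0), n_nodes = integer(0),
                      w_crit = integer(0), seed = integer(0),
                      n_edges = integer(0), n_examined = integer(0),
                      dp_steps = numeric(0), n_paths = numeric(0),
                      n_intractable = integer(0)))
  rows <- list()
  for (spec in models) {
    if (is.null(spec$model))
      stop("each model specification needs a 'model' entry", call. = FALSE)
    label <- spec$label
    for (nv in sizes) {
      for (sd in seeds) {
        g <- switch(spec$model,
          random = gen_random(nv, spec$rho, w_max = w_max, seed = sd),
          smallworld = gen_small_world(nv, spec$neighbors, spec$p_rewire,
                                       w_max = w_max, seed = sd),
          scalefree = gen_scale_free(nv, spec$m, w_max = w_max, seed = sd),
          stop("unknown model: ", spec$model, call. = FALSE))
        if (is.null(label))
          label <- switch(spec$model,
                          random = sprintf("random(rho=%g)", spec$rho),
                          smallworld = sprintf("smallworld(n=%d,p=%g)",
                                               spec$neighbors, spec$p_rewire),
                          scalefree = sprintf("scalefree(m=%d)", spec$m))
        et <- edge_table(g)
        take <- seq_len(min(nrow(et), max_edges))
        for (wc in w_crit_values) {
          dp_steps <- 0; n_paths <- 0; n_intr <- 0L
          for (i in take) {
            theta_e <- max(0L, wc - et$delay[i])
            res <- find_alternative_paths(g, c(et$source[i], et$target[i]),
                                          theta_e, limit = limit)
            dp_steps <- dp_steps + res$dp_steps
            n_paths <- n_paths + res$n_paths
            n_intr <- n_intr + res$intractable
          }
          rows[[length(rows) + 1L]] <- data.frame(
            model = label, n_nodes = as.integer(nv), w_crit = as.integer(wc),
            seed = as.integer(sd), n_edges = nrow(et),
            n_examined = length(take), dp_steps = dp_steps,
            n_paths = n_paths, n_intractable = n_intr,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
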