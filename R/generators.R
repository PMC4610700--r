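# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Weights are drawn after the topology, in edge-lexicographic order, so
# that the topology is comparable across w_max settings at a fixed seed.
weight_edges <- function(from, to, w_max) {
  o <- order(from, to)
  from <- from[o]; to <- to[o]
  w <- if (length(from)) sample.int(w_max, length(from), replace = TRUE)
       else integer(0)
  list(from = from, to = to, w = w)
}

check_gen_params <- function(n_nodes, w_max, seed) {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1 || n_nodes < 2 ||
      n_nodes != round(n_nodes))
    stop("n_nodes must be an integer >= 2", call. = FALSE)
  if (!is.numeric(w_max) || length(w_max) != 1 || w_max < 1 ||
      w_max != round(w_max))
    stop("w_max must be an integer >= 1", call. = FALSE)
  if (!is.null(seed) && (!is.numeric(seed) || length(seed) != 1))
    stop("seed must be a single number or NULL", call. = FALSE)
}

#' Generate a directed weighted small-world network
#'
#' Directed, weighted modification of the Watts–Strogatz rule:
#' \enumerate{
#'   \item a regular ring lattice on `n_nodes` vertices where each vertex
#'     \eqn{v_i} sends a directed edge to its `neighbors` nearest ring
#'     neighbors \eqn{v_{i\pm 1}, \dots, v_{i\pm neighbors/2}} (indices
#'     modulo `n_nodes`);
#'   \item each edge \eqn{(v_i, v_j)} is independently rewired with
#'     probability `p_rewire` to \eqn{(v_i, v_k)} with \eqn{k} uniform on
#'     \eqn{V \setminus \{v_i\}}, redrawn until it creates neither a
#'     self-loop nor a duplicate edge;
#'   \item each edge gets a weight drawn uniformly from `1..w_max`.
#' }
#' Only the underlying undirected, unweighted lattice has textbook
#' small-world properties; this directed weighted variant is an
#' approximation suited to delay-weighted interaction networks.
#'
#' The default `w_max = 17` mirrors the upper end of interaction delays
#' typically reconstructed from MEG data (5–17 ms at millisecond
#' resolution) and is configurable.
#'
#' @param n_nodes number of vertices (>= 3).
#' @param neighbors even per-node neighborhood coefficient
#'   (< `n_nodes`); the out-degree of every node before rewiring.
#' @param p_rewire rewiring probability in \[0, 1\].
#' @param w_max maximum integer edge weight.
#' @param seed optional integer seed; identical seeds give identical
#'   graphs.
#' @return a `delay_digraph` with labels `"1".."n_nodes"`.
#' @export
gen_small_world <- function(n_nodes, neighbors, p_rewire, w_max = 17,
                            seed = NULL) {
  check_gen_params(n_nodes, w_max, seed)
  if (n_nodes < 3) stop("n_nodes must be >= 3", call. = FALSE)
  if (!is.numeric(neighbors) || neighbors %% 2 != 0 || neighbors < 2 ||
      neighbors >= n_nodes)
    stop("neighbors must be even, >= 2 and < n_nodes", call. = FALSE)
  if (!is.numeric(p_rewire) || p_rewire < 0 || p_rewire > 1)
    stop("p_rewire must be in [0, 1]", call. = FALSE)
  n <- as.integer(n_nodes)
  half <- neighbors / 2
  with_seed(seed, {
    A <- matrix(FALSE, n, n)
    ring <- vector("list", n)
    for (i in seq_len(n)) {
      offs <- c(seq_len(half), -seq_len(half))
      targets <- ((i - 1L + offs) %% n) + 1L
      A[i, targets] <- TRUE
      ring[[i]] <- targets
    }
    # rewire in deterministic construction order
    for (i in seq_len(n)) {
      for (j in ring[[i]]) {
        if (stats::runif(1) < p_rewire) {
          A[i, j] <- FALSE
          repeat {
            k <- sample.int(n - 1L, 1L)
            k <- if (k >= i) k + 1L else k      # uniform on V \ {i}
            if (!A[i, k]) break
          }
          A[i, k] <- TRUE
        }
      }
    }
    hit <- which(A, arr.ind = TRUE)
    we <- weight_edges(hit[, 1], hit[, 2], w_max)
    delay_digraph(we$from, we$to, we$w, labels = as.character(seq_len(n)))
  })
}

#' Generate a directed weighted random network
#'
#' Each of the `n_nodes * (n_nodes - 1)` ordered vertex pairs is included
#' independently with probability `rho` (the density, Erdos–Renyi
#' G(n, p) on ordered pairs); weights are uniform on `1..w_max`.
#'
#' @param n_nodes number of vertices (>= 2).
#' @param rho edge-inclusion probability / expected density in \[0, 1\].
#' @inheritParams gen_small_world
#' @return a `delay_digraph` with labels `"1".."n_nodes"`.
#' @export
gen_random <- function(n_nodes, rho, w_max = 17, seed = NULL) {
  check_gen_params(n_nodes, w_max, seed)
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho > 1)
    stop("rho must be in [0, 1]", call. = FALSE)
  n <- as.integer(n_nodes)
  with_seed(seed, {
    from <- rep(seq_len(n), each = n)
    to <- rep(seq_len(n), times = n)
    off <- from != to                       # ordered pairs, lexicographic
    from <- from[off]; to <- to[off]
    keep <- stats::runif(length(from)) < rho
    we <- weight_edges(from[keep], to[keep], w_max)
    delay_digraph(we$from, we$to, we$w, labels = as.character(seq_len(n)))
  })
}

#' Generate a directed weighted scale-free network
#'
#' Barabási–Albert-style preferential attachment adapted to directed
#' weighted graphs under the following (documented, fixed) convention:
#' the seed graph is a complete digraph on `m + 1` vertices; each
#' subsequently added vertex attaches `m` directed edges (from the new
#' vertex to `m` distinct existing vertices) chosen with probability
#' proportional to current total (in + out) degree; weights are uniform
#' on `1..w_max`. Under this convention the edge count is exactly
#' `m * n_nodes` — the seed clique contributes `m(m+1)` edges and each of
#' the `n_nodes - m - 1` later vertices contributes `m`. Total degrees
#' follow an (emergent) heavy-tailed distribution.
#'
#' @param n_nodes number of vertices (> `m`).
#' @param m number of edges attached per new vertex (>= 1).
#' @inheritParams gen_small_world
#' @return a `delay_digraph` with labels `"1".."n_nodes"`.
#' @export
gen_scale_free <- function(n_nodes, m, w_max = 17, seed = NULL) {
  check_gen_params(n_nodes, w_max, seed)
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m != round(m) ||
      m >= n_nodes)
    stop("m must be an integer with 1 <= m < n_nodes", call. = FALSE)
  n <- as.integer(n_nodes); m <- as.integer(m)
  with_seed(seed, {
    from <- rep(seq_len(m + 1L), each = m + 1L)
    to <- rep(seq_len(m + 1L), times = m + 1L)
    keep <- from != to
    from <- from[keep]; to <- to[keep]
    deg <- integer(n)
    deg[seq_len(m + 1L)] <- 2L * m
    if (n > m + 1L) {
      for (v in (m + 2L):n) {
        existing <- seq_len(v - 1L)
        targets <- sample(existing, m, prob = deg[existing])
        from <- c(from, rep.int(v, m))
        to <- c(to, targets)
        deg[targets] <- deg[targets] + 1L
        deg[v] <- m
      }
    }
    we <- weight_edges(from, to, w_max)
    delay_digraph(we$from, we$to, we$w, labels = as.character(seq_len(n)))
  })
}

#' Expected number of alternative paths in a random network
#'
#' Analytic estimate of the number of weight-constrained alternative
#' paths in a dense random network, used to reason about path
#' proliferation: summed over candidate path weights
#' \eqn{w' = 1..w_{crit}} and edge counts \eqn{j = 1..w'},
#' \deqn{\sum_{w'=1}^{w_{crit}} \sum_{j=1}^{w'} \binom{w'-1}{j-1}
#'       \left(\frac{\rho}{w_{max}}\right)^{j},}
#' where \eqn{\binom{w'-1}{j-1}} counts the compositions of \eqn{w'} into
#' \eqn{j} parts, \eqn{\rho} is the edge probability and \eqn{1/w_{max}}
#' the probability of a given edge weight. The expression is evaluated
#' exactly as stated (the per-step weight probability is taken as
#' \eqn{1/w_{max}} regardless of the \eqn{w \le w_{max}} bound); it is
#' intended for the regime \eqn{w_{crit} > |V|} and grows as
#' \eqn{\Omega(2^{w_{crit}})} at \eqn{\rho = 1, w_{max} = 1}.
#'
#' @param rho edge probability in \[0, 1\].
#' @param w_max maximum edge weight (integer >= 1).
#' @param w_crit critical path weight (integer >= 1).
#' @return expected path count (non-negative real).
#' @export
expected_alt_path_count <- function(rho, w_max, w_crit) {
  if (!is.numeric(rho) || rho < 0 || rho > 1)
    stop("rho must be in [0, 1]", call. = FALSE)
  if (!is.numeric(w_max) || w_max < 1 || w_max != round(w_max))
    stop("w_max must be an integer >= 1", call. = FALSE)
  if (!is.numeric(w_crit) || w_crit < 1 || w_crit != round(w_crit))
    stop("w_crit must be an integer >= 1", call. = FALSE)
  q <- rho / w_max
  total <- 0
  for (wp in seq_len(w_crit)) {
    j <- seq_len(wp)
    total <- total + sum(choose(wp - 1, j - 1) * q^j)
  }
  total
}

#' Number of compositions of an integer
#'
#' The number of ordered sequences of positive integers summing to `i`,
#' \eqn{\sum_{j=1}^{i} \binom{i-1}{j-1} = 2^{i-1}} — the growth driver of
#' the alternative-path count in dense networks.
#'
#' @param i positive integer.
#' @return the composition count (exact for `i <= 50`).
#' @export
compositions_count <- function(i) {
  if (!is.numeric(i) || length(i) != 1 || i < 1 || i != round(i))
    stop("i must be a positive integer", call. = FALSE)
  sum(choose(i - 1, seq_len(i) - 1))
}
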