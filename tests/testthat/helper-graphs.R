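# Small fixture graphs built in code, plus independent oracle helpers
# shared across test files.

triangle_graph <- function() {
  delay_digraph(c("1", "2", "1"), c("2", "3", "3"), c(3, 4, 7))
}

# 1 -> 2 -> 3 -> 4 chain plus a direct 1 -> 4 edge
cascade_graph <- function(w_direct = 9) {
  delay_digraph(c("1", "2", "3", "1"), c("2", "3", "4", "4"),
                c(2, 3, 4, w_direct))
}

# contains the 2 -> 3 -> 2 cycle: the only weight-4 route 1 ~> 4 is the
# looping walk <1,2,3,2,4>
cycle_graph <- function() {
  delay_digraph(c("1", "2", "3", "2", "1"), c("2", "3", "2", "4", "4"),
                c(1, 1, 1, 1, 4))
}

# two length-2 alternatives 1->2->3 and 1->4->3 to the direct 1->3 edge
diamond_graph <- function() {
  delay_digraph(c("1", "1", "2", "4", "1"), c("2", "4", "3", "3", "3"),
                c(3, 3, 4, 4, 7))
}

complete_digraph <- function(n, w = 1) {
  from <- rep(seq_len(n), each = n)
  to <- rep(seq_len(n), times = n)
  keep <- from != to
  delay_digraph(as.character(from[keep]), as.character(to[keep]),
                rep(w, sum(keep)), labels = as.character(seq_len(n)))
}

# canonical keys for set comparison of path collections
path_keys <- function(paths) {
  sort(vapply(paths, function(p)
    paste0(paste(p$vertices, collapse = ","), "|", p$total_weight),
    character(1)))
}

# assert every alternative path satisfies its invariants
expect_valid_alt_paths <- function(res, graph) {
  lo <- res$w_edge - res$theta
  hi <- res$w_edge + res$theta
  for (p in res$paths) {
    expect_false(anyDuplicated(p$vertices) > 0)
    expect_identical(p$vertices[1], res$edge[1])
    expect_identical(p$vertices[length(p$vertices)], res$edge[2])
    expect_gte(p$graphical_length, 2)
    expect_identical(p$graphical_length, length(p$vertices) - 1L)
    w <- 0L
    for (i in seq_len(length(p$vertices) - 1L)) {
      ei <- spurnet:::edge_index(graph, p$vertices[i], p$vertices[i + 1])
      expect_false(is.na(ei))
      w <- w + graph$edges$w[ei]
    }
    expect_identical(w, as.integer(p$total_weight))
    expect_true(p$total_weight >= lo && p$total_weight <= hi)
  }
  invisible(res)
}

# independent enumeration of all compositions of i (ordered sequences of
# positive integers summing to i)
enumerate_compositions <- function(i) {
  if (i == 0) return(list(integer(0)))
  out <- list()
  for (first in seq_len(i)) {
    for (rest in enumerate_compositions(i - first)) {
      out[[length(out) + 1L]] <- c(first, rest)
    }
  }
  out
}

# Eq-style expected path count evaluated by explicit composition
# enumeration instead of binomial coefficients (independent oracle)
expected_count_by_enumeration <- function(rho, w_max, w_crit) {
  q <- rho / w_max
  total <- 0
  for (wp in seq_len(w_crit)) {
    for (comp in enumerate_compositions(wp)) total <- total + q^length(comp)
  }
  total
}
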