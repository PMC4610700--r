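test_that("preprocessing removes the edge, reorders vertices and sets w_crit", {
  g <- triangle_graph()
  inst <- preprocess_edge(g, c("1", "3"), theta = 0)
  expect_s3_class(inst, "problem_instance")
  expect_identical(inst$w_crit, 7L)
  expect_identical(inst$labels[1], "1")
  expect_identical(inst$labels[inst$n], "3")
  # G' = {(1,2), (2,3)} in new indexing
  expect_identical(nrow(inst$edges), 2L)
  expect_setequal(paste(inst$edges$from, inst$edges$to, inst$edges$w),
                  c("1 2 3", "2 3 4"))
  expect_identical(preprocess_edge(g, c("1", "3"), theta = 1)$w_crit, 8L)

  two <- delay_digraph("1", "2", 5)
  inst2 <- preprocess_edge(two, c("1", "2"), 0)
  expect_identical(nrow(inst2$edges), 0L)
  expect_identical(inst2$w_crit, 5L)

  expect_error(preprocess_edge(g, c("3", "1"), 0), "not in graph")
  expect_error(preprocess_edge(g, c("1", "3"), -1), "non-negative")
})

test_that("the solution array holds exactly the reachable walk weights", {
  inst <- preprocess_edge(triangle_graph(), c("1", "3"), 0)
  arr <- solve_subproblems(inst)
  nonempty <- which(arr$nonempty, arr.ind = TRUE)
  # cells (weight, vertex): only (0,1), (3,2), (7,3)  [rows are weight+1]
  expect_setequal(paste(nonempty[, 1] - 1, nonempty[, 2]),
                  c("0 1", "3 2", "7 3"))
  # tuple content: cell (3,2) = {(3,1)}, cell (7,3) = {(4,2)}
  t32 <- spurnet:::cell_tuples(arr, inst, 3L, 2L)
  expect_identical(cbind(inst$edges$w[t32], inst$edges$from[t32]),
                   cbind(3L, 1L))
  t73 <- spurnet:::cell_tuples(arr, inst, 7L, 3L)
  expect_identical(cbind(inst$edges$w[t73], inst$edges$from[t73]),
                   cbind(4L, 2L))

  two <- preprocess_edge(delay_digraph("1", "2", 5), c("1", "2"), 0)
  arr2 <- solve_subproblems(two)
  expect_identical(sum(arr2$nonempty), 1L)
  expect_true(arr2$nonempty[1, 1])
})

test_that("walks with vertex repeats are represented at the DP level", {
  g <- cycle_graph()
  inst <- preprocess_edge(g, c("1", "4"), 0)
  arr <- solve_subproblems(inst)
  # the weight-4 walk <1,2,3,2,4> reaches v_t: cell (4, v_t) non-empty
  expect_true(arr$nonempty[5, inst$n])
  ids <- spurnet:::cell_tuples(arr, inst, 4L, inst$n)
  expect_identical(inst$edges$w[ids], 1L)
  expect_identical(inst$labels[inst$edges$from[ids]], "2")
  # ... but its only expansion repeats vertex 2: no valid simple path
  res <- backtrack_paths(arr, inst, limit = 20000)
  expect_identical(res$n_paths, 0L)
  expect_false(res$has_alternative)
  expect_gt(res$n_loop_discards, 0L)
})

test_that("solution cells match the brute-force walk oracle", {
  for (i in 1:25) {
    g <- gen_random(6, 0.45, w_max = 4, seed = 300 + i)
    et <- edge_table(g)
    if (!nrow(et)) next
    e <- c(et$source[1], et$target[1])
    inst <- preprocess_edge(g, e, theta = 2)
    arr <- solve_subproblems(inst)
    for (v in 2:inst$n) {
      for (w in 0:inst$w_crit) {
        expect_identical(
          arr$nonempty[w + 1, v],
          walk_exists(g, e[1], inst$labels[v], w, exclude_edge = e),
          info = sprintf("seed %d v=%s w=%d", 300 + i, inst$labels[v], w))
      }
    }
  }
})

test_that("full search returns exactly the in-interval simple paths", {
  res <- find_alternative_paths(triangle_graph(), c("1", "3"), 0)
  expect_identical(res$n_paths, 1L)
  expect_identical(res$paths[[1]]$vertices, c("1", "2", "3"))
  expect_identical(res$paths[[1]]$total_weight, 7L)

  res9 <- find_alternative_paths(cascade_graph(9), c("1", "4"), 0)
  expect_identical(path_keys(res9$paths), "1,2,3,4|9")
  res8 <- find_alternative_paths(cascade_graph(8), c("1", "4"), 0)
  expect_identical(res8$n_paths, 0L)
  res81 <- find_alternative_paths(cascade_graph(8), c("1", "4"), 1)
  expect_identical(path_keys(res81$paths), "1,2,3,4|9")
})

test_that("search agrees with the simple-path oracle on random graphs", {
  for (i in 1:40) {
    n <- 4 + (i %% 5)
    rho <- if (i %% 2) 0.3 else 0.5
    theta <- i %% 3
    g <- gen_random(n, rho, w_max = 6, seed = 700 + i)
    et <- edge_table(g)
    for (j in seq_len(nrow(et))) {
      e <- c(et$source[j], et$target[j])
      res <- find_alternative_paths(g, e, theta)
      expect_valid_alt_paths(res, g)
      oracle <- enumerate_simple_paths(
        g, e[1], e[2], max(0, et$delay[j] - theta), et$delay[j] + theta,
        exclude_edge = e)
      expect_identical(path_keys(res$paths), path_keys(oracle),
                       info = sprintf("seed %d edge %s->%s theta %d",
                                      700 + i, e[1], e[2], theta))
    }
  }
})

test_that("algorithmic steps equal w_crit times |E(G')|", {
  for (i in 1:10) {
    g <- gen_random(7, 0.5, w_max = 5, seed = 40 + i)
    et <- edge_table(g)
    for (j in seq_len(min(5, nrow(et)))) {
      theta <- i %% 3
      res <- find_alternative_paths(g, c(et$source[j], et$target[j]), theta)
      expect_identical(res$dp_steps,
                       as.integer((et$delay[j] + theta) * (nrow(et) - 1L)))
    }
  }
})

test_that("vertex relabeling permutes the path sets and nothing else", {
  g <- gen_random(7, 0.5, w_max = 5, seed = 99)
  perm <- c("f", "a", "d", "g", "b", "c", "e")  # new label of vertex i
  et <- edge_table(g)
  gp <- delay_digraph(perm[as.integer(et$source)],
                      perm[as.integer(et$target)], et$delay,
                      labels = perm[as.integer(g$labels)])
  for (j in seq_len(nrow(et))) {
    e <- c(et$source[j], et$target[j])
    r1 <- find_alternative_paths(g, e, 1)
    r2 <- find_alternative_paths(gp, perm[as.integer(e)], 1)
    mapped <- lapply(r1$paths, function(p) {
      p$vertices <- perm[as.integer(p$vertices)]; p
    })
    expect_identical(path_keys(mapped), path_keys(r2$paths))
  }
})

test_that("the reconstruction limit flags intractable instances", {
  res <- find_alternative_paths(diamond_graph(), c("1", "3"), 0, limit = 1)
  expect_true(res$intractable)
  expect_true(res$has_alternative)
  expect_identical(res$n_paths, 1L)
  res2 <- find_alternative_paths(diamond_graph(), c("1", "3"), 0, limit = 3)
  expect_false(res2$intractable)  # 2 paths exist, below the limit
  expect_identical(res2$n_paths, 2L)
  expect_error(find_alternative_paths(triangle_graph(), c("1", "3"), 0,
                                      limit = 0), "positive integer")
})
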