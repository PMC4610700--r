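test_that("cascade-effect tagging flags exactly the bridged edges", {
  res <- tag_cascade_effects(triangle_graph(), theta = 0)
  expect_identical(paste(res$ce_edges$source, res$ce_edges$target), "1 3")

  res2 <- tag_cascade_effects(cascade_graph(9), theta = 0)
  expect_identical(paste(res2$ce_edges$source, res2$ce_edges$target), "1 4")

  empty <- delay_digraph(character(0), character(0), integer(0),
                         labels = c("a", "b"))
  expect_identical(nrow(tag_cascade_effects(empty, 0)$ce_edges), 0L)
  single <- delay_digraph("a", "b", 3)
  expect_identical(nrow(tag_cascade_effects(single, 0)$ce_edges), 0L)
})

test_that("triangle motifs yield common-drive tags on the second edge", {
  res <- tag_spurious_edges(triangle_graph(), theta = 0)
  expect_identical(paste(res$cd_edges$source, res$cd_edges$target), "2 3")
  tt <- tags_table(res)
  expect_setequal(paste(tt$source, tt$target, tt$tag),
                  c("1 3 CE", "2 3 CD"))
  expect_identical(nrow(res$triangles), 1L)
  expect_identical(res$triangles$v_1, "2")

  # alternative path of length 3: no CD tag
  res2 <- tag_spurious_edges(cascade_graph(9), theta = 0)
  expect_identical(nrow(res2$cd_edges), 0L)

  # diamond: two triangles, CD on both second edges
  res3 <- tag_spurious_edges(diamond_graph(), theta = 0)
  expect_identical(paste(res3$ce_edges$source, res3$ce_edges$target), "1 3")
  expect_setequal(paste(res3$cd_edges$source, res3$cd_edges$target),
                  c("2 3", "4 3"))
  expect_identical(nrow(res3$triangles), 2L)
})

test_that("every CD triangle satisfies the timing condition arithmetically", {
  for (i in 1:15) {
    g <- gen_random(7, 0.5, w_max = 5, seed = 880 + i)
    theta <- i %% 3
    res <- tag_spurious_edges(g, theta)
    tri <- res$triangles
    for (k in seq_len(nrow(tri))) {
      s <- tri$w_s1[k] + tri$w_1t[k]
      expect_true(abs(s - tri$w_st[k]) <= theta)
      # all three edges present
      expect_false(is.na(spurnet:::edge_index(g, tri$v_s[k], tri$v_1[k])))
      expect_false(is.na(spurnet:::edge_index(g, tri$v_1[k], tri$v_t[k])))
      expect_false(is.na(spurnet:::edge_index(g, tri$v_s[k], tri$v_t[k])))
      # the triangle's direct edge is CE-tagged
      expect_true(paste(tri$v_s[k], tri$v_t[k]) %in%
                    paste(res$ce_edges$source, res$ce_edges$target))
    }
  }
})

test_that("an isolated consistent triangle tags exactly 2 of 3 edges", {
  expect_identical(nrow(tags_table(tag_spurious_edges(triangle_graph(), 0))),
                   2L)
})

test_that("pruning follows the policy and logs removals", {
  g <- triangle_graph()
  res <- tag_spurious_edges(g, 0)
  all_p <- prune_graph(g, res, "all")
  expect_identical(paste(edge_table(all_p)$source, edge_table(all_p)$target),
                   "1 2")
  expect_identical(nrow(attr(all_p, "removed")), 2L)
  expect_identical(nrow(attr(all_p, "mutually_exclusive")), 1L)
  ce_p <- prune_graph(g, res, "ce-only")
  expect_setequal(paste(edge_table(ce_p)$source, edge_table(ce_p)$target),
                  c("1 2", "2 3"))
  cd_p <- prune_graph(g, res, "cd-only")
  expect_setequal(paste(edge_table(cd_p)$source, edge_table(cd_p)$target),
                  c("1 2", "1 3"))
  ro <- prune_graph(g, res, "report-only")
  expect_true(graph_identical(ro, g))

  untagged <- cascade_graph(5)  # direct weight 5 has no matching path
  res_u <- tag_spurious_edges(untagged, 0)
  expect_true(graph_identical(prune_graph(untagged, res_u, "all"), untagged))

  expect_error(prune_graph(diamond_graph(), res, "all"), "different graph")
})

test_that("growing theta can only grow the CE set", {
  for (i in 1:12) {
    g <- gen_random(7, 0.4, w_max = 5, seed = 1200 + i)
    prev <- character(0)
    for (theta in 0:3) {
      res <- tag_cascade_effects(g, theta)
      cur <- paste(res$ce_edges$source, res$ce_edges$target)
      expect_true(all(prev %in% cur),
                  info = sprintf("seed %d theta %d", 1200 + i, theta))
      prev <- cur
    }
  }
})

test_that("pruning all tags leaves nothing retaggable", {
  for (i in 1:12) {
    g <- gen_random(7, 0.4, w_max = 5, seed = 1300 + i)
    theta <- i %% 3
    pruned <- prune_graph(g, tag_spurious_edges(g, theta), "all")
    res2 <- tag_cascade_effects(pruned, theta)
    expect_identical(nrow(res2$ce_edges), 0L,
                     info = sprintf("seed %d theta %d", 1300 + i, theta))
  }
})

test_that("tagging is equivariant under vertex relabeling", {
  g <- gen_random(6, 0.5, w_max = 4, seed = 77)
  perm <- c("q", "w", "e", "r", "t", "y")
  et <- edge_table(g)
  gp <- delay_digraph(perm[as.integer(et$source)],
                      perm[as.integer(et$target)], et$delay,
                      labels = perm[as.integer(g$labels)])
  r1 <- tag_spurious_edges(g, 1)
  r2 <- tag_spurious_edges(gp, 1)
  expect_setequal(paste(perm[as.integer(r1$ce_edges$source)],
                        perm[as.integer(r1$ce_edges$target)]),
                  paste(r2$ce_edges$source, r2$ce_edges$target))
  expect_setequal(paste(perm[as.integer(r1$cd_edges$source)],
                        perm[as.integer(r1$cd_edges$target)]),
                  paste(r2$cd_edges$source, r2$cd_edges$target))
})

test_that("limit-hit edges stay CE-tagged and are flagged intractable", {
  res <- tag_spurious_edges(diamond_graph(), 0, limit = 1)
  expect_true("1 3" %in% paste(res$ce_edges$source, res$ce_edges$target))
  expect_identical(paste(res$intractable_edges$source,
                         res$intractable_edges$target), "1 3")
  tt <- tags_table(res)
  expect_true(tt$intractable[tt$source == "1" & tt$target == "3"])
  expect_error(tag_cascade_effects(diamond_graph(), 0, limit = 1,
                                   on_limit = "abort"),
               class = "spurnet_limit_abort")
})
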