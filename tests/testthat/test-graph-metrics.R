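test_that("shortest distances use inverse-weight lengths and handle unreachable pairs", {
  tri <- mat_from_edges(3, list(c(1, 2, .5), c(2, 3, .5), c(1, 3, .1)))
  d <- shortest_distances(tri)
  # two-hop route 1/.5 + 1/.5 = 4 beats the direct edge 1/.1 = 10
  expect_equal(d[1, 3], 4)
  expect_equal(d[1, 2], 2)
  expect_true(isSymmetric(d))

  k4 <- complete_graph(4)
  expect_true(all(shortest_distances(k4)[upper.tri(diag(4))] == 1))

  two_comp <- mat_from_edges(4, list(c(1, 2, 1), c(3, 4, 1)))
  expect_equal(shortest_distances(two_comp)[1, 3], Inf)
})

test_that("distances and betweenness match exhaustive path enumeration on small graphs", {
  withr::with_seed(42, {
    for (rep in 1:12) {
      n <- sample(5:8, 1)
      x <- er_graph(n, 0.5, weighted = TRUE)
      if (sum(unclass(x) > 0) < 2) next
      oracle <- brute_force_paths(x)
      expect_equal(shortest_distances(x), oracle$distances,
                   tolerance = 1e-9)
      expect_equal(nodal_metrics(x)$bc, oracle$betweenness,
                   tolerance = 1e-9)
    }
  })
})

test_that("nodal metrics reproduce closed forms on canonical graphs", {
  st <- star_graph(4)   # 5 nodes, center first
  nm <- nodal_metrics(st)
  expect_equal(nm$bc[1], 6)             # (n-1)(n-2)/2 leaf pairs
  expect_true(all(nm$bc[-1] == 0))
  expect_equal(nm$dc[1], 4)

  tri <- complete_graph(3)
  expect_true(all(nodal_metrics(tri)$ncc == 1))

  p3 <- path_graph(3)
  nm3 <- nodal_metrics(p3)
  expect_equal(nm3$ne[1], (1 / 1 + 1 / 2) / 2)  # distances 1 and 2
  expect_equal(nm3$nlp[2], 1)

  expect_error(nodal_metrics(connectivity_matrix(matrix(0, 2, 2))), "3 nodes")
})

test_that("nodal efficiency and path length satisfy the Jensen inequality", {
  withr::with_seed(17, {
    for (rep in 1:10) {
      x <- er_graph(12, 0.5, weighted = TRUE)
      if (any(shortest_distances(x) == Inf)) next
      nm <- nodal_metrics(x)
      expect_true(all(nm$ne >= 1 / nm$nlp - 1e-12))
    }
  })
})

test_that("weight scaling scales distances and leaves rank structure alone", {
  withr::with_seed(23, {
    x <- er_graph(10, 0.5, weighted = TRUE)
    c_ <- 3.7
    xs <- connectivity_matrix(unclass(x) * c_)
    expect_equal(shortest_distances(xs), shortest_distances(x) / c_)
    nm <- nodal_metrics(x); nms <- nodal_metrics(xs)
    expect_equal(nms$bc, nm$bc)
    expect_equal(nms$dc, nm$dc)
    expect_equal(nodal_metrics(xs, "binary")$ncc,
                 nodal_metrics(x, "binary")$ncc)
    expect_equal(order(nms$ne), order(nm$ne))
  })
})

test_that("global metrics reproduce closed forms", {
  k4 <- complete_graph(4)
  g <- global_metrics(k4, nulls = NULL)
  expect_equal(g$eglob, 1)
  expect_equal(g$cp, 1)

  p3 <- path_graph(3)
  expect_equal(global_metrics(p3, nulls = NULL)$lp, 4 / 3)

  expect_error(global_metrics(connectivity_matrix(matrix(0, 3, 3)),
                              nulls = NULL), "edgeless")
})

test_that("degree-preserving rewiring keeps the degree sequence and carries weights", {
  withr::with_seed(3, {
    x <- er_graph(20, 0.3, weighted = TRUE)
    r <- rewire_preserving_degree(x, null_model_config(1, 10, seed = 77))
    expect_equal(rowSums(unclass(r) > 0), rowSums(unclass(x) > 0))
    # the multiset of edge weights is preserved
    expect_equal(sort(unclass(r)[unclass(r) > 0]),
                 sort(unclass(x)[unclass(x) > 0]))
    expect_gt(attr(r, "n_swaps"), 0)

    # determinism under the same seed
    r2 <- rewire_preserving_degree(x, null_model_config(1, 10, seed = 77))
    expect_identical(unclass(r), unclass(r2))

    # a triangle admits no valid swap and is returned unchanged
    tri <- complete_graph(3)
    rt <- rewire_preserving_degree(tri, null_model_config(1, 10, seed = 1))
    expect_equal(unclass(rt), unclass(tri), ignore_attr = TRUE)
  })
})

test_that("small-worldness separates lattices from random graphs and is ~1 for ER", {
  nulls <- null_model_config(n_null = 20, seed = 101)
  lattice <- ring_lattice(50, 4)
  rg <- withr::with_seed(55, er_graph(50, 4 / 49))
  sig_lat <- global_metrics(lattice, nulls = nulls)$sigma
  sig_rnd <- global_metrics(rg, nulls = nulls)$sigma
  expect_gt(sig_lat, sig_rnd)
  expect_gt(sig_lat, 1)

  er30 <- withr::with_seed(60, er_graph(30, 0.3, weighted = TRUE))
  sig_er <- global_metrics(er30, nulls = null_model_config(20, 10, 9))$sigma
  expect_lt(abs(sig_er - 1), 0.15)

  # reproducible given the config seed
  g1 <- global_metrics(er30, nulls = null_model_config(5, 10, 4))
  g2 <- global_metrics(er30, nulls = null_model_config(5, 10, 4))
  expect_identical(g1, g2)
})

test_that("AUC aggregation over a sparsity grid matches the trapezoid rule", {
  expect_equal(auc_over_sparsity(c(1, 3), c(0.1, 0.2)), 0.2)
  expect_equal(auc_over_sparsity(c(2, 2, 2), c(0.1, 0.2, 0.3)), 0.4)
  grid <- default_sparsity_grid()
  expect_equal(auc_over_sparsity(rep(1, length(grid)), grid),
               max(grid) - min(grid))
})
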