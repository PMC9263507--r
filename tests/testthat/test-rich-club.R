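test_that("rich-club coefficient matches closed forms and flags undefined clubs", {
  # K4 plus a pendant node: at k = 1 the club is the 4-clique
  k4p <- mat_from_edges(5, list(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1),
                                c(2, 3, 1), c(2, 4, 1), c(3, 4, 1),
                                c(4, 5, 1)))
  rc <- rich_club_coefficient(k4p, 1)
  expect_equal(rc$n_club, 4)
  expect_equal(rc$phi, 1)

  k5 <- complete_graph(5)
  for (k in 0:3) {
    rc5 <- rich_club_coefficient(k5, k)
    expect_equal(rc5$phi, 1)
    expect_equal(rc5$phi_w, 1)
  }

  # star: only the center has degree > 1, club of size 1 is undefined
  st <- star_graph(4)
  rc1 <- rich_club_coefficient(st, 1)
  expect_false(rc1$defined)
  expect_true(is.na(rc1$phi))
})

test_that("phi is scale-invariant while phi_w scales linearly with the weights", {
  withr::with_seed(8, {
    x <- er_graph(15, 0.4, weighted = TRUE)
    xs <- connectivity_matrix(unclass(x) * 2.5)
    c1 <- rich_club_curve(x)
    c2 <- rich_club_curve(xs)
    expect_equal(c2$phi, c1$phi)
    expect_equal(c2$phi_w, c1$phi_w * 2.5)
  })
})

test_that("normalized rich club is ~1 for ER graphs and >1 for a planted core", {
  er <- er_graph(40, 0.25, seed = 14)
  rc <- normalized_rich_club(er, null_model_config(20, 10, seed = 2))
  mid <- rc[rc$defined & rc$n_club >= 5 & rc$n_club <= 35, ]
  expect_gt(nrow(mid), 3)
  expect_lt(mean(abs(mid$phi_norm - 1)), 0.1)

  planted <- planted_club_graph(seed = 19)
  rcp <- normalized_rich_club(planted, null_model_config(20, 10, seed = 3))
  tail_k <- rcp[rcp$defined & rcp$n_club <= 15 & rcp$n_club >= 3, ]
  expect_gt(mean(tail_k$phi_norm), 1)

  # determinism under the same null seed
  rc2 <- normalized_rich_club(er, null_model_config(20, 10, seed = 2))
  expect_identical(rc, rc2)
})

test_that("hub identification applies the 1-SD rule and top-k selection", {
  # averaged degrees [10,10,10,2,2,2,2,2]: mean 5, population SD sqrt(15)
  prof_edges <- function() {
    w <- matrix(0, 8, 8)
    # nodes 1:3 in a triangle with high multiplicity via weights only;
    # build exact degrees instead with a handcrafted profile matrix
    w
  }
  # single synthetic subject whose degree profile is exactly the target:
  # connect nodes 1-3 to 10 others is impossible at N=8, so feed the rule
  # through two matrices whose average produces the profile
  m <- matrix(0, 16, 16)
  for (hub in 1:3) for (other in setdiff(1:11, hub)) m[hub, other] <- m[other, hub] <- 1
  # nodes 1:3 now have degree 10; give nodes 4:16 degree adjustments
  x <- connectivity_matrix(m)
  hs <- identify_hubs(list(x), method = "sd_rule")
  prof <- hs$mean_degree
  expect_equal(prof[1:3], rep(10, 3))
  manual_thr <- mean(prof) + sqrt(mean((prof - mean(prof))^2))
  expect_equal(hs$threshold, manual_thr)
  expect_true(all(1:3 %in% hs$hubs))
  expect_true(all(prof[hs$hubs] >= manual_thr))

  topk <- identify_hubs(list(x), method = "top_k", k_top = 3)
  expect_equal(sort(topk$hubs), 1:3)

  # ties at the boundary resolve to the smaller node index
  tie <- mat_from_edges(5, list(c(1, 2, 1), c(3, 4, 1), c(4, 5, 1)))
  t2 <- identify_hubs(list(tie), method = "top_k", k_top = 2)
  expect_equal(t2$hubs, c(4, 1))   # degree 2 first, then tied degree-1 node 1

  expect_error(identify_hubs(list(x, complete_graph(4))), "mixed")
})

test_that("edge classification partitions edges by hub endpoints", {
  x <- mat_from_edges(6, list(c(1, 2, .5), c(1, 3, .4), c(3, 4, .3),
                              c(4, 5, .2), c(5, 6, .6)))
  cls <- classify_edges(x, hubs = c(1, 2))
  expect_equal(cls$class[cls$i == 1 & cls$j == 2], "rich_club")
  expect_equal(cls$class[cls$i == 1 & cls$j == 3], "feeder")
  expect_equal(cls$class[cls$i == 4 & cls$j == 5], "local")
  expect_equal(nrow(cls), 5)   # partition: counts sum to the edge count
  expect_equal(sum(table(cls$class)), 5)

  # empty hub set: everything is local
  cls0 <- classify_edges(x, hubs = integer(0))
  expect_true(all(cls0$class == "local"))
})

test_that("per-node abnormal-connection counts satisfy the handshake identity", {
  ab <- data.frame(i = c(1, 1, 7, 7, 7, 7, 7),
                   j = c(2, 3, 1, 2, 3, 4, 5),
                   direction = c("increased", "decreased", rep("increased", 5)))
  cnt <- count_abnormal_per_node(ab, n_nodes = 8)
  expect_equal(cnt$n_total[cnt$node == 7], 5)
  expect_equal(cnt$n_increased[cnt$node == 1], 2)
  expect_equal(cnt$n_decreased[cnt$node == 1], 1)
  expect_equal(sum(cnt$n_total), 2 * nrow(ab))

  cnt0 <- count_abnormal_per_node(ab[0, ], n_nodes = 4)
  expect_true(all(cnt0$n_total == 0))
})

test_that("top-13 selection recovers planted hubs on a synthetic cohort", {
  co <- generate_cohort(cohort_config(seed = 404))
  hubs <- identify_hubs(co$matrices, method = "top_k", k_top = 13)
  expect_setequal(hubs$hubs, co$truth$hub_nodes)
  sd_hubs <- identify_hubs(co$matrices, method = "sd_rule")
  expect_true(all(co$truth$hub_nodes %in% sd_hubs$hubs))
})
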