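test_that("CWN is zero without common neighbours and counts them correctly", {
  # path A-B-C-D: A and D share no neighbour
  net <- toy_path(c("A", "B", "C", "D"))
  expect_equal(cwn(net, "A", "D"), 0)
  # unit-weight triangle plus pendant, hand evaluation:
  # common neighbour of (A, C) is B, contribution (1 + 1) / d_w(B) = 2/2 = 1
  tri <- toy_triangle_pendant()
  expect_equal(cwn(tri, "A", "C"), 1)
  # weighted variant: w(AB)=2 w(BC)=3 w(CA)=1 w(AD)=4
  # cwn(B, C) via common neighbour A: (2 + 1) / (2 + 1 + 4) = 3/7
  triw <- toy_triangle_pendant(weights = c(2, 3, 1, 4))
  expect_equal(cwn(triw, "B", "C"), 3 / 7)
  # cwn(A, C) via B: (2 + 3) / (2 + 3) = 1
  expect_equal(cwn(triw, "A", "C"), 1)
})

test_that("CWN strictly increases when a common neighbour is added", {
  net1 <- build_network(data.frame(a = c("A", "B"), b = c("X", "X")))
  base <- cwn(net1, "A", "B")
  net2 <- build_network(data.frame(a = c("A", "B", "A", "B"),
                                   b = c("X", "X", "Y", "Y")))
  expect_gt(cwn(net2, "A", "B"), base)
})

test_that("CWN is symmetric on random graphs and errors on unknown nodes", {
  for (s in 1:5) {
    net <- random_connected_net(8, 0.4, seed = s, weighted = TRUE)
    ids <- network_nodes(net)
    prs <- t(utils::combn(ids, 2))
    for (r in seq_len(nrow(prs))) {
      expect_equal(cwn(net, prs[r, 1], prs[r, 2]),
                   cwn(net, prs[r, 2], prs[r, 1]))
    }
  }
  expect_error(cwn(toy_path(), "A", "Q"), "unknown protein")
})

test_that("closed-form diffusion states match the truncated-walk oracle", {
  # damped walks on bipartite fixtures (the un-damped partial sums
  # oscillate on bipartite graphs), un-damped on non-bipartite ones
  p3 <- toy_path(c("A", "B", "C"))
  st <- diffusion_states(p3, gamma = 0.9)
  for (pr in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    expect_equal(ds_distance(st, pr[1], pr[2]),
                 walk_oracle_distance(p3, pr[1], pr[2], gamma = 0.9),
                 tolerance = 1e-6)
  }
  c4 <- toy_cycle(4)
  st4 <- diffusion_states(c4, gamma = 0.85)
  expect_equal(ds_distance(st4, "A", "C"),
               walk_oracle_distance(c4, "A", "C", gamma = 0.85),
               tolerance = 1e-6)
  tri <- toy_triangle_pendant()
  st_t <- diffusion_states(tri, gamma = 1)
  for (pr in list(c("A", "B"), c("B", "D"), c("C", "D"))) {
    expect_equal(ds_distance(st_t, pr[1], pr[2]),
                 walk_oracle_distance(tri, pr[1], pr[2], gamma = 1),
                 tolerance = 1e-6)
  }
})

test_that("diffusion distance identity, symmetry and disconnected error", {
  st <- diffusion_states(toy_triangle_pendant())
  expect_equal(ds_distance(st, "A", "A"), 0)
  expect_equal(ds_distance(st, "A", "D"), ds_distance(st, "D", "A"))
  two_comp <- build_network(data.frame(a = c("A", "C"), b = c("B", "D")))
  expect_error(diffusion_states(two_comp), "per connected component")
})

test_that("diffusion distance satisfies the metric axioms on small graphs", {
  for (s in 1:4) {
    net <- random_connected_net(7, 0.45, seed = s + 10)
    st <- diffusion_states(net)
    ids <- network_nodes(net)
    X <- st$states
    for (i in ids) for (j in ids) {
      dij <- ds_distance(st, i, j)
      expect_gte(dij, 0)
      expect_equal(dij, ds_distance(st, j, i))
      if (i != j && any(X[i, ] != X[j, ])) expect_gt(dij, 0)
    }
    trip <- t(utils::combn(ids, 3))
    for (r in seq_len(nrow(trip))) {
      a <- trip[r, 1]; b <- trip[r, 2]; cc <- trip[r, 3]
      expect_lte(ds_distance(st, a, cc),
                 ds_distance(st, a, b) + ds_distance(st, b, cc) + 1e-12)
    }
  }
})

test_that("global proximity is symmetric, positive, and respects automorphisms", {
  c4 <- toy_cycle(4)
  st <- diffusion_states(c4)
  # B and D are automorphic images with respect to A
  expect_equal(global_proximity(st, "A", "B"), global_proximity(st, "A", "D"))
  expect_equal(global_proximity(st, "A", "C"), global_proximity(st, "C", "A"))
  expect_gt(global_proximity(st, "A", "C"), 0)
  expect_error(global_proximity(st, "A", "A"), "self-pairs")
  # reciprocal of the oracle distance (damped variant on this bipartite graph)
  stg <- diffusion_states(c4, gamma = 0.9)
  u <- global_proximity(stg, "A", "C")
  expect_equal(u, 1 / walk_oracle_distance(c4, "A", "C", gamma = 0.9),
               tolerance = 1e-6)
})

test_that("GLIDE composes its local and global parts per the aggregation rule", {
  net <- random_connected_net(6, 0.5, seed = 3, weighted = TRUE)
  ids <- network_nodes(net)
  st <- diffusion_states(net)
  params <- glide_params()  # alpha 0.1, beta 1000
  prs <- t(utils::combn(ids, 2))
  for (r in seq_len(nrow(prs))) {
    p <- prs[r, 1]; q <- prs[r, 2]
    u <- global_proximity(st, p, q)
    manual <- exp(params$alpha * u / (u + params$beta)) * cwn(net, p, q) + u
    expect_equal(glide(net, p, q, params), manual, tolerance = 1e-12)
    expect_equal(glide(net, p, q, params), glide(net, q, p, params))
  }
})

test_that("GLIDE reduces to the global term when no neighbours are shared", {
  net <- toy_path(c("A", "B", "C", "D"))
  st <- diffusion_states(net)
  expect_identical(glide(net, "A", "D"), global_proximity(st, "A", "D"))
})

test_that("alpha = 0 collapses the multiplier", {
  net <- toy_triangle_pendant()
  st <- diffusion_states(net)
  p0 <- glide_params(alpha = 0)
  expect_equal(glide(net, "A", "C", p0),
               cwn(net, "A", "C") + global_proximity(st, "A", "C"))
})

test_that("the exponential multiplier stays in (1, exp(alpha)] for u > 0", {
  net <- random_connected_net(8, 0.4, seed = 5)
  st <- diffusion_states(net)
  params <- glide_params(alpha = 0.7, beta = 10)
  ids <- network_nodes(net)
  prs <- t(utils::combn(ids, 2))
  for (r in seq_len(nrow(prs))) {
    u <- global_proximity(st, prs[r, 1], prs[r, 2])
    mult <- exp(params$alpha * u / (u + params$beta))
    expect_gt(mult, 1)
    expect_lte(mult, exp(params$alpha))
  }
})

test_that("cross-component pairs fall back to the local term, no exception", {
  net <- build_network(data.frame(a = c("A", "B", "X"), b = c("B", "C", "Y")))
  expect_equal(glide(net, "A", "X"), 0)  # no shared neighbours, u = 0
  tab <- glide_table(net, data.frame(id_a = "A", id_b = "X"))
  expect_equal(tab$score, 0)
  expect_false(tab$off_network)
})

test_that("glide_table preserves order, flags off-network pairs, matches loops", {
  net <- random_connected_net(10, 0.35, seed = 7, weighted = TRUE)
  ids <- network_nodes(net)
  prs <- withr::with_seed(8, {
    all <- t(utils::combn(ids, 2))
    all[sample(nrow(all), 20), ]
  })
  tab <- glide_table(net, prs)
  expect_equal(nrow(tab), 20)
  loop <- vapply(seq_len(20), function(i) glide(net, prs[i, 1], prs[i, 2]),
                 0.0)
  expect_equal(tab$score, loop)
  # off-network endpoint: flagged, scored 0
  tab2 <- glide_table(net, data.frame(id_a = c(ids[1], "ZZZ"),
                                      id_b = c(ids[2], ids[3])))
  expect_equal(tab2$off_network, c(FALSE, TRUE))
  expect_equal(tab2$score[2], 0)
  # empty list
  expect_equal(nrow(glide_table(net, data.frame(id_a = character(),
                                                id_b = character()))), 0)
})

test_that("percentile thresholds follow the inclusive interpolation rule", {
  tab <- structure(data.frame(id_a = "a", id_b = "b", score = 1,
                              off_network = FALSE),
                   class = c("glide_table", "data.frame"))
  expect_error(percentile_threshold(tab, 0), "percentile")
  expect_error(percentile_threshold(tab, 100), "percentile")
  scores <- as.numeric(1:100)
  expect_equal(percentile_threshold(scores, 50), stats::median(scores))
  expect_equal(percentile_threshold(scores, 99.9999), 100, tolerance = 1e-3)
  expect_silent(percentile_threshold(scores, 92.5))
  # monotone non-decreasing in g_t
  ths <- vapply(seq(5, 95, by = 5),
                function(g) percentile_threshold(scores, g), 0.0)
  expect_true(all(diff(ths) >= 0))
  # fraction of scores >= threshold is (100 - g_t)/100 up to interpolation
  thr <- percentile_threshold(scores, 92.5)
  expect_lt(abs(mean(scores >= thr) - 0.075), 0.011)
})
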