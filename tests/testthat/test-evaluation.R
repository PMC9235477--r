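test_that("AUPR matches the exhaustive threshold-sweep oracle", {
  labels <- c(1, 0, 1, 0)
  scores <- c(0.9, 0.8, 0.7, 0.1)
  expect_equal(aupr(labels, scores), aupr_oracle(labels, scores))
  expect_equal(aupr(c(1, 1, 0, 0), c(4, 3, 2, 1)), 1.0)
  withr::with_seed(13, {
    for (i in 1:20) {
      n <- sample(4:12, 1)
      lab <- c(1, 0, rbinom(n - 2, 1, 0.4))
      sc <- round(runif(n), 1)  # coarse grid forces ties
      expect_equal(aupr(lab, sc), aupr_oracle(lab, sc))
    }
  })
  expect_error(aupr(c(1, 1), c(0.5, 0.2)), "both classes")
})

test_that("AUROC equals the concordance probability, ties included", {
  expect_equal(auroc(c(1, 1, 0, 0), c(4, 3, 2, 1)), 1.0)
  labels <- c(1, 0, 1, 0)
  scores <- c(0.9, 0.8, 0.7, 0.1)
  expect_equal(auroc(labels, scores), auroc_oracle(labels, scores))
  withr::with_seed(17, {
    for (i in 1:20) {
      n <- sample(4:12, 1)
      lab <- c(1, 0, rbinom(n - 2, 1, 0.4))
      sc <- round(runif(n), 1)
      expect_equal(auroc(lab, sc), auroc_oracle(lab, sc))
    }
  })
})

test_that("AUROC agrees with an established independent implementation", {
  withr::with_seed(23, {
    for (i in 1:5) {
      lab <- c(1, 0, rbinom(60, 1, 0.25))
      sc <- c(runif(31), round(runif(31), 1))
      ref <- as.numeric(suppressMessages(
        pROC::auc(pROC::roc(lab, sc, direction = "<", quiet = TRUE))))
      expect_equal(auroc(lab, sc), ref, tolerance = 1e-12)
    }
  })
})

test_that("rank metrics are invariant under strictly monotone transforms", {
  withr::with_seed(5, {
    lab <- rbinom(40, 1, 0.3); lab[1] <- 1; lab[2] <- 0
    sc <- rnorm(40)
    for (f in list(function(x) 3 * x + 2, exp,
                   function(x) x^3)) {
      expect_equal(aupr(lab, f(sc)), aupr(lab, sc))
      expect_equal(auroc(lab, f(sc)), auroc(lab, sc))
    }
  })
})

test_that("random scores at 1:10 imbalance give AUPR ~ prevalence, AUROC ~ 0.5", {
  res <- withr::with_seed(99, {
    t(replicate(60, {
      lab <- rep(c(1, 0), c(100, 1000))
      sc <- runif(1100)
      c(aupr(lab, sc), auroc(lab, sc))
    }))
  })
  expect_lt(abs(mean(res[, 1]) - 1 / 11), 0.012)
  expect_lt(abs(mean(res[, 2]) - 0.5), 0.01)
})

test_that("FPR at recall follows the sweep oracle and degenerate rules", {
  lab <- c(1, 1, 1, 0, 0, 0, 0, 1, 0, 0)
  sc <- c(0.9, 0.85, 0.3, 0.8, 0.7, 0.2, 0.1, 0.75, 0.75, 0.05)
  for (lev in c(0.1, 0.5, 1)) {
    expect_equal(fpr_at_recall(lab, sc, lev), fpr_oracle(lab, sc, lev))
  }
  expect_equal(fpr_at_recall(c(1, 0, 1, 0), c(1, 0.1, 0.9, 0.2), 0.5), 0)
  # all scores tied: every achievable recall costs the full FPR
  expect_equal(fpr_at_recall(c(1, 0, 0), c(1, 1, 1), 0.5), 1)
  expect_error(fpr_at_recall(lab, sc, 1.5), "recall_level")
})

test_that("max-degree stratification uses the documented bins", {
  hub_edges <- data.frame(a = "HUB", b = sprintf("x%02d", 1:30))
  extra <- data.frame(a = c("x01", "x02", "x03", "x02"),
                      b = c("x02", "x03", "x04", "x05"))
  net <- build_network(rbind(hub_edges, extra))
  pairs <- data.frame(id_a = c("HUB", "x01", "x04", "x10"),
                      id_b = c("x20", "x03", "x05", "x11"))
  strata <- stratify_by_max_degree(pairs, net)
  expect_equal(strata[[">=21"]]$id_a, "HUB")
  # degrees: x01 = 2, x03 = 3 -> bin 2-5 ; x04 = 2, x05 = 2 -> 2-5
  expect_equal(nrow(strata[["2-5"]]), 2)
  # spoke-spoke pair of two degree-1 nodes falls in the underflow stratum
  expect_equal(strata[["<2"]]$id_a, "x10")
  got <- do.call(rbind, unname(strata))
  expect_setequal(glideppi:::pair_key(got$id_a, got$id_b),
                  glideppi:::pair_key(pairs$id_a, pairs$id_b))
  expect_equal(sum(vapply(strata, nrow, 0L)), nrow(pairs))
  expect_error(stratify_by_max_degree(data.frame(id_a = "HUB",
                                                 id_b = "nope"), net),
               "not in the network")
})

test_that("distance stratification matches BFS distances", {
  c6 <- toy_cycle(6)
  pairs <- data.frame(id_a = c("A", "A", "A"), id_b = c("B", "C", "D"))
  strata <- stratify_by_distance(pairs, c6)
  expect_equal(strata[["1"]]$id_b, "B")
  expect_equal(strata[["2"]]$id_b, "C")
  expect_equal(strata[["3"]]$id_b, "D")  # opposite nodes of a 6-cycle
  two <- build_network(data.frame(a = c("A", "X"), b = c("B", "Y")))
  s2 <- stratify_by_distance(data.frame(id_a = c("A", "A"),
                                        id_b = c("B", "X")), two)
  expect_equal(s2[["Inf"]]$id_b, "X")
})

test_that("hub filtering removes pairs at the strict degree-21 boundary", {
  mk_star <- function(center, n) data.frame(a = center,
                                            b = paste0(center, seq_len(n)))
  net <- build_network(rbind(mk_star("h21", 21), mk_star("d20", 20),
                             data.frame(a = "h21", b = "d20")))
  # degrees: h21 = 22, d20 = 21 after the connecting edge... rebuild cleanly
  net <- build_network(rbind(mk_star("h", 21), mk_star("k", 20),
                             data.frame(a = "h1", b = "k1")))
  deg <- network_degree(net)
  expect_equal(unname(deg["h"]), 21)
  expect_equal(unname(deg["k"]), 20)
  pairs <- data.frame(id_a = c("h", "k", "k"), id_b = c("k1", "k1", "k2"))
  kept <- filter_hub_edges(pairs, net, cutoff = 21)
  expect_false("h" %in% kept$id_a)        # degree 21 endpoint removed
  expect_equal(nrow(kept), 2)             # degree-20 endpoints survive
  removed <- pairs[!(glideppi:::pair_key(pairs$id_a, pairs$id_b) %in%
                       glideppi:::pair_key(kept$id_a, kept$id_b)), ]
  expect_equal(nrow(kept) + nrow(removed), nrow(pairs))
})

test_that("sparsification keeps a spanning tree and the exact edge budget", {
  net <- random_connected_net(20, 0.3, seed = 31)
  ne <- unname(network_size(net)["edges"])
  s1 <- sparsify(net, p = 1, seed = 1)
  expect_equal(network_edges(s1$net), network_edges(net))
  expect_equal(nrow(s1$held_out), 0)
  for (seed in 1:10) {
    p <- withr::with_seed(seed, runif(1, 0.45, 0.95))
    sp <- sparsify(net, p, seed = seed)
    expect_true(igraph::is_connected(sp$net$g))
    expect_equal(unname(network_size(sp$net)["edges"]), floor(p * ne + 0.5))
    expect_equal(nrow(sp$held_out), ne - floor(p * ne + 0.5))
  }
  expect_error(sparsify(net, p = 0.05, seed = 1), "feasible minimum")
  expect_error(sparsify(net, p = 1.2, seed = 1), "\\(0, 1\\]")
})

test_that("sparsified test sets satisfy both set identities", {
  net <- random_connected_net(40, 0.08, seed = 8)
  sp <- sparsify(net, 0.6, seed = 2)
  ts <- sparsified_testset(net, sp, ratio = 10, seed = 3)
  full <- glideppi:::pair_key(network_edges(net)$id_a,
                              network_edges(net)$id_b)
  kept <- glideppi:::pair_key(network_edges(sp$net)$id_a,
                              network_edges(sp$net)$id_b)
  posk <- glideppi:::pair_key(ts$positives$id_a, ts$positives$id_b)
  expect_setequal(posk, setdiff(full, kept))
  negk <- glideppi:::pair_key(ts$negatives$id_a, ts$negatives$id_b)
  expect_length(intersect(negk, full), 0)
  expect_equal(nrow(ts$negatives), 10 * nrow(ts$positives))
  expect_equal(nrow(ts$labels), nrow(ts$positives) + nrow(ts$negatives))
})

test_that("evaluation reports assemble and serialise", {
  lab <- c(1, 1, 0, 0, 0, 1, 0, 0)
  sc <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.85, 0.1, 0.05)
  rep <- evaluate(lab, sc)
  expect_equal(rep$aupr, aupr(lab, sc))
  expect_equal(rep$auroc, auroc(lab, sc))
  expect_equal(rep$fpr_at$fpr_at_0.1, fpr_at_recall(lab, sc, 0.1))
  expect_equal(rep$n_pos, 3)
  perfect <- evaluate(c(1, 0, 1, 0), c(1, 0, 0.9, 0.1))
  expect_equal(perfect$aupr, 1)
  expect_equal(perfect$auroc, 1)
  expect_equal(perfect$fpr_at$fpr_at_0.5, 0)
  # strata must partition
  rep2 <- evaluate(lab, sc, strata = list(a = 1:4, b = 5:8))
  expect_named(rep2$strata, c("a", "b"))
  expect_error(evaluate(lab, sc, strata = list(a = 1:3)), "partition")
  f <- withr::local_tempfile(fileext = ".json")
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep, f, tsv = ft)
  got <- jsonlite::read_json(f)
  expect_equal(got$aupr, rep$aupr)
  expect_equal(got$`fpr_at_0.5`, rep$fpr_at$fpr_at_0.5)
  expect_true(file.exists(ft))
})
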