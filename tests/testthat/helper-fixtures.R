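# Shared fixtures and independent oracles, all built in code.

# triangle A-B-C plus pendant D on A, unit weights
toy_triangle_pendant <- function(weights = c(1, 1, 1, 1)) {
  build_network(data.frame(a = c("A", "B", "C", "A"),
                           b = c("B", "C", "A", "D"),
                           w = weights))
}

toy_path <- function(ids = c("A", "B", "C")) {
  n <- length(ids)
  build_network(data.frame(a = ids[-n], b = ids[-1], w = 1))
}

toy_cycle <- function(n = 4) {
  ids <- LETTERS[seq_len(n)]
  build_network(data.frame(a = ids, b = c(ids[-1], ids[1]), w = 1))
}

# Erdos-Renyi-ish random connected graph for property tests
random_connected_net <- function(n, p = 0.4, seed = 1, weighted = FALSE) {
  withr::with_seed(seed, {
    repeat {
      ids <- paste0("n", seq_len(n))
      pairs <- t(utils::combn(ids, 2))
      pick <- runif(nrow(pairs)) < p
      if (sum(pick) < n - 1) next
      df <- data.frame(a = pairs[pick, 1], b = pairs[pick, 2],
                       w = if (weighted) round(runif(sum(pick), 0.5, 3), 2)
                           else 1)
      net <- build_network(df, nodes = ids)
      if (igraph::components(net$g)$no == 1L) return(net)
    }
  })
}

# Truncated damped random-walk oracle for the diffusion state distance:
# D_k(p,q) = || sum_{s=0..k} gamma^s (e_p - e_q)' P^s ||_1, built from the
# edge table alone (independent of the package's closed form).
walk_oracle_distance <- function(net, p, q, gamma = 1, k = 5000) {
  ed <- network_edges(net)
  ids <- network_nodes(net)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (r in seq_len(nrow(ed))) {
    A[ed$id_a[r], ed$id_b[r]] <- ed$weight[r]
    A[ed$id_b[r], ed$id_a[r]] <- ed$weight[r]
  }
  P <- A / rowSums(A)
  v <- numeric(n); names(v) <- ids
  v[p] <- 1; v[q] <- -1
  acc <- v; cur <- v
  for (s in seq_len(k)) {
    cur <- as.numeric(cur %*% P) * gamma
    acc <- acc + cur
  }
  sum(abs(acc))
}

is_bipartite_net <- function(net) {
  # bipartite_mapping can error on named non-bipartite graphs
  isTRUE(tryCatch(igraph::bipartite_mapping(net$g)$res,
                  error = function(e) FALSE))
}

# Exhaustive threshold-sweep AUPR oracle (step-wise, tie groups)
aupr_oracle <- function(labels, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  area <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / sum(labels == 1)
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# Brute-force concordant-pair AUROC oracle (ties count 1/2)
auroc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# FPR-at-recall threshold-sweep oracle
fpr_oracle <- function(labels, scores, level) {
  thr <- sort(unique(scores), decreasing = TRUE)
  for (t in thr) {
    sel <- scores >= t
    rec <- sum(labels[sel] == 1) / sum(labels == 1)
    if (rec >= level) return(sum(labels[sel] == 0) / sum(labels == 0))
  }
  NA_real_
}

# Desk-scale benchmark conditions used by the training experiments
desk_benchmark_config <- function(noise_fraction = 0) {
  synth_benchmark_config(length_range = c(30, 60),
                         noise_fraction = noise_fraction)
}

desk_model <- function(seed, embedder = hash_embedder()) {
  cfg <- model_config(projection_dim = 20, hidden_dim = 10,
                      conv_width = 7, pool_width = 9, seed = seed,
                      embedder_tag = embedder_tag(embedder))
  seq_model(cfg, embed_dim = embedder_dim(embedder))
}

# One full training run on the desk benchmark; returns best validation AUPR
desk_training_run <- function(seed, g_p, noise_fraction = 0, epochs = 10) {
  bench <- synth_benchmark(desk_benchmark_config(noise_fraction), seed = seed)
  embedder <- hash_embedder()
  emb <- embed_proteins(bench$sequences, embedder)
  ex <- make_glide_targets(network_edges(bench$network)[, 1:2], bench$train)
  fit <- train_model(desk_model(seed, embedder), ex, emb,
                     loss_config(g_p = g_p),
                     train_config(epochs = epochs, seed = seed),
                     validation = bench$val)
  list(best_val_aupr = max(fit$history$val_aupr), fit = fit, bench = bench)
}
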