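# Seeded synthetic benchmark generators.
#
# The generators emulate the aspects of real interaction data the rest of
# the package depends on: degree-heterogeneous undirected networks with
# hubs and communities, a strong negative:positive class imbalance
# (default 10:1), and sequence pairs whose labels carry learnable sequence
# signal (interacting proteins share community-specific motifs). Every
# generator is a pure function of (config, seed).

#' Generate a degree-heterogeneous community network
#'
#' Mixes a preferential-attachment backbone (producing hub nodes) with
#' planted communities densified by within-community random edges, then
#' wires any stray components back to the giant component. With n >= 200
#' and the default hub fraction the degree distribution spans the 2-5 /
#' 6-10 / 11-20 / >=21 strata, including true hubs (degree >= 21).
#'
#' @param n_nodes number of proteins (>= 10)
#' @param hub_fraction fraction of nodes boosted into hubs (default 0.05)
#' @param community_count number of planted communities (default 5)
#' @param p_within within-community edge probability (default 0.08)
#' @param backbone_m edges added per node by the preferential-attachment
#'   backbone (default 2; 1 gives a sparser tree-like backbone)
#' @param seed integer seed
#' @return a `ppi_network` with a `communities` attribute (named integer
#'   vector)
#' @export
synth_network <- function(n_nodes, hub_fraction = 0.05, community_count = 5,
                          p_within = 0.08, backbone_m = 2, seed = 1) {
  assert_that(n_nodes >= 10, "n_nodes must be >= 10")
  assert_that(hub_fraction >= 0 && hub_fraction <= 0.5,
              "hub_fraction must be in [0, 0.5]")
  assert_that(community_count >= 1 && community_count <= n_nodes / 2,
              "infeasible community_count")
  ids <- sprintf("P%04d", seq_len(n_nodes))
  el <- withr::with_seed(seed, {
    g0 <- igraph::sample_pa(n_nodes, power = 1, m = backbone_m,
                            directed = FALSE)
    edges <- igraph::as_edgelist(g0)
    comm <- sample(community_count, n_nodes, replace = TRUE)
    # densify communities
    for (cmt in seq_len(community_count)) {
      members <- which(comm == cmt)
      if (length(members) < 2) next
      pairs <- utils::combn(members, 2)
      pick <- runif(ncol(pairs)) < p_within
      if (any(pick)) edges <- rbind(edges, t(pairs[, pick, drop = FALSE]))
    }
    # hub boost: attach extra random partners to a few chosen nodes
    n_hubs <- round(hub_fraction * n_nodes)
    if (n_hubs > 0) {
      hubs <- sample(n_nodes, n_hubs)
      for (hb in hubs) {
        extra <- sample(setdiff(seq_len(n_nodes), hb),
                        min(n_nodes - 1L, 18L + sample.int(8L, 1L)))
        edges <- rbind(edges, cbind(hb, extra))
      }
    }
    list(edges = edges, comm = comm)
  })
  df <- data.frame(a = ids[el$edges[, 1]], b = ids[el$edges[, 2]], w = 1,
                   stringsAsFactors = FALSE)
  df <- df[df$a != df$b, ]
  df <- df[!duplicated(pair_key(df$a, df$b)), ]
  net <- build_network(df, nodes = ids)
  # connect stray components deterministically to the giant one
  comps <- igraph::components(net$g)
  if (comps$no > 1L) {
    giant <- which.max(comps$csize)
    anchors <- ids[comps$membership == giant][1]
    fix <- vapply(setdiff(seq_len(comps$no), giant), function(cid) {
      ids[comps$membership == cid][1]
    }, "")
    df <- rbind(df, data.frame(a = fix, b = anchors, w = 1))
    net <- build_network(df, nodes = ids)
  }
  communities <- setNames(el$comm, ids)
  attr(net, "communities") <- communities
  net
}

random_aa <- function(n) {
  paste(sample(AA_ALPHABET[1:20], n, replace = TRUE), collapse = "")
}

#' Benchmark configuration
#'
#' @param n_nodes,hub_fraction,community_count,p_within,backbone_m network
#'   parameters (see [synth_network()])
#' @param negative_ratio negatives per positive (default 10)
#' @param noise_fraction fraction of negatives replaced by planted
#'   truly-positive pairs mislabelled 0 (default 0); planted pairs are
#'   chosen preferentially between nodes with many common neighbours so
#'   their GLIDE scores are high
#' @param length_range sequence-length range (default c(50, 300))
#' @param motif_length length of the interface motifs (default 8)
#' @param split train/val/test proportions (must sum to 1)
#' @export
synth_benchmark_config <- function(n_nodes = 70, hub_fraction = 0.04,
                                   community_count = 4, p_within = 0.08,
                                   backbone_m = 1,
                                   negative_ratio = 10, noise_fraction = 0,
                                   length_range = c(50, 300),
                                   motif_length = 8,
                                   split = c(train = 0.7, val = 0.15,
                                             test = 0.15)) {
  assert_that(abs(sum(split) - 1) < 1e-9, "split proportions must sum to 1")
  assert_that(noise_fraction >= 0 && noise_fraction < 0.5,
              "noise_fraction must be in [0, 0.5)")
  assert_that(length_range[1] >= 20 && length_range[2] >= length_range[1],
              "invalid length_range")
  list(n_nodes = n_nodes, hub_fraction = hub_fraction,
       community_count = community_count, p_within = p_within,
       backbone_m = backbone_m,
       negative_ratio = negative_ratio, noise_fraction = noise_fraction,
       length_range = length_range, motif_length = motif_length,
       split = split)
}

#' Generate a complete synthetic benchmark
#'
#' Draws a network, assigns each protein a sequence carrying interface
#' motifs of its interactions (interacting pairs thus share a compatible
#' motif pair, giving the sequence model learnable signal; hub proteins
#' carry only a capped subset, leaving their interactions
#' sequence-ambiguous), labels network edges positive, samples negatives at
#' the configured ratio, optionally plants mislabelled truly-positive pairs
#' among the training negatives, and splits everything into pair-disjoint
#' train/val/test sets.
#'
#' @param config a [synth_benchmark_config()]
#' @param seed integer seed; the benchmark is a pure function of
#'   (config, seed)
#' @return a `synthetic_benchmark`: network, sequences, communities, motifs,
#'   train/val/test example data.frames (id_a, id_b, label), planted pairs,
#'   config, seed
#' @export
synth_benchmark <- function(config = synth_benchmark_config(), seed = 1) {
  net <- synth_network(config$n_nodes, config$hub_fraction,
                       config$community_count, config$p_within,
                       backbone_m = config$backbone_m, seed = seed)
  communities <- attr(net, "communities")
  ids <- network_nodes(net)
  edges <- network_edges(net)[, c("id_a", "id_b")]
  withr::with_seed(seed + 1L, {
    n_pos <- nrow(edges)
    negatives <- sample_negatives(ids, edges, ratio = config$negative_ratio,
                                  seed = seed + 2L)
    # planted mislabels: non-edge pairs with many common neighbours, same
    # community (so the sequence generator treats them as true interactions)
    planted <- data.frame(id_a = character(), id_b = character())
    n_plant <- round(config$noise_fraction * nrow(negatives))
    if (n_plant > 0) {
      cand <- candidate_high_cwn_nonedges(net, communities, n_plant * 8L)
      # spread planted pairs across proteins (at most 2 per protein) so
      # their interface motifs fit within the per-protein slot capacity
      cand <- cap_pairs_per_node(cand, 2L)
      assert_that(nrow(cand) >= n_plant,
                  sprintf("only %d high-common-neighbour non-edges available for %d planted mislabels",
                          nrow(cand), n_plant))
      planted <- cand[sample(nrow(cand), n_plant), , drop = FALSE]
      rownames(planted) <- NULL
      # substitute planted pairs for sampled negatives (dropping collisions)
      pk <- pair_key(planted$id_a, planted$id_b)
      rest <- negatives[!(pair_key(negatives$id_a, negatives$id_b)
                          %in% pk), , drop = FALSE]
      negatives <- utils::head(rbind(planted, rest),
                               config$negative_ratio * n_pos)
    }
    # interaction partners for the sequence generator: edges + planted.
    # Each true pair carries its own interface motif, written into both
    # endpoint sequences (up to a per-protein slot capacity, so hub
    # proteins carry only a subset and their interactions remain
    # sequence-ambiguous).
    true_pairs <- rbind(edges, planted)
    motifs <- setNames(vapply(seq_len(nrow(true_pairs)), function(i)
      random_aa(config$motif_length), ""),
      pair_key(true_pairs$id_a, true_pairs$id_b))
    # planted pairs keep their motifs with priority under the slot cap:
    # the mislabelling experiment needs them to stay sequence-positive
    seqs <- synth_sequences(ids, true_pairs, motifs, config,
                            priority_keys = pair_key(planted$id_a,
                                                     planted$id_b))
    # splits: positives and negatives split separately; planted mislabels
    # are forced into the training negatives
    split_idx <- function(n, props) {
      k <- floor(props * n)
      k[1] <- n - sum(k[-1])
      rep(names(props), k)[sample.int(n)]
    }
    pos_split <- split_idx(n_pos, config$split)
    pk <- pair_key(planted$id_a, planted$id_b)
    is_planted <- pair_key(negatives$id_a, negatives$id_b) %in% pk
    neg_split <- character(nrow(negatives))
    neg_split[is_planted] <- "train"
    neg_split[!is_planted] <- split_idx(sum(!is_planted), config$split)
    mk <- function(part) {
      ex <- rbind(
        data.frame(edges[pos_split == part, , drop = FALSE], label = 1),
        data.frame(negatives[neg_split == part, , drop = FALSE], label = 0))
      rownames(ex) <- NULL
      ex
    }
    structure(list(network = net, sequences = seqs,
                   communities = communities, motifs = motifs,
                   train = mk("train"), val = mk("val"), test = mk("test"),
                   planted = planted, config = config, seed = seed),
              class = "synthetic_benchmark")
  })
}

# Non-edge pairs with >= 2 common neighbours (so their CWN, and hence
# GLIDE, scores are high), ordered by common-neighbour count.
candidate_high_cwn_nonedges <- function(net, communities, max_n) {
  A <- igraph::as_adjacency_matrix(net$g, sparse = TRUE)
  cn <- A %*% A
  ids <- network_nodes(net)
  idx <- Matrix_which_upper(cn >= 2)
  a <- ids[idx[, 1]]; b <- ids[idx[, 2]]
  keep <- !mapply(has_edge, a, b, MoreArgs = list(net = net))
  counts <- as.matrix(cn)[idx][keep]
  out <- data.frame(id_a = a[keep], id_b = b[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-counts), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, max_n)
}

# greedy pass keeping at most `budget` pairs per node, preserving order
cap_pairs_per_node <- function(pairs, budget) {
  used <- integer(0)
  keep <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    a <- pairs$id_a[r]; b <- pairs$id_b[r]
    ca <- if (a %in% names(used)) used[[a]] else 0L
    cb <- if (b %in% names(used)) used[[b]] else 0L
    if (ca < budget && cb < budget) {
      keep[r] <- TRUE
      used[a] <- ca + 1L
      used[b] <- cb + 1L
    }
  }
  pairs[keep, , drop = FALSE]
}

# which() over the strict upper triangle of a sparse logical matrix
Matrix_which_upper <- function(m) {
  w <- which(as.matrix(m), arr.ind = TRUE)
  w[w[, 1] < w[, 2], , drop = FALSE]
}

# Sequences: uniform random background with each protein's interface
# motifs written over random non-overlapping slots.
synth_sequences <- function(ids, true_pairs, motifs, config,
                            priority_keys = character()) {
  keys <- pair_key(true_pairs$id_a, true_pairs$id_b)
  partner_motifs <- lapply(setNames(ids, ids), function(x) character())
  for (r in seq_len(nrow(true_pairs))) {
    a <- true_pairs$id_a[r]; b <- true_pairs$id_b[r]
    partner_motifs[[a]] <- c(partner_motifs[[a]], keys[r])
    partner_motifs[[b]] <- c(partner_motifs[[b]], keys[r])
  }
  ml <- config$motif_length
  gap <- ml + 4L
  vapply(ids, function(id) {
    L <- config$length_range[1] +
      sample.int(config$length_range[2] - config$length_range[1] + 1L, 1L) - 1L
    s <- strsplit(random_aa(L), "")[[1]]
    wanted <- unique(partner_motifs[[id]])
    slots <- seq(1L, L - ml + 1L, by = gap)
    if (length(wanted) > length(slots)) {
      prio <- intersect(wanted, priority_keys)
      rest <- setdiff(wanted, prio)
      ord <- c(prio, rest[sample.int(length(rest))])
      wanted <- utils::head(ord, length(slots))
    }
    if (length(wanted)) {
      pos <- slots[sample.int(length(slots), length(wanted))]
      for (i in seq_along(wanted)) {
        s[pos[i]:(pos[i] + ml - 1L)] <- strsplit(motifs[[wanted[i]]], "")[[1]]
      }
    }
    paste(s, collapse = "")
  }, "")
}

#' Motif co-occurrence baseline score
#'
#' Scores a pair by the number of community motifs present in both
#' sequences. A deliberately trivial probe: if this baseline beats the
#' random AUPR baseline on a benchmark's test split, the benchmark carries
#' learnable sequence signal.
#'
#' @param bench a `synthetic_benchmark`
#' @param pairs data.frame id_a, id_b
#' @export
motif_cooccurrence_score <- function(bench, pairs) {
  df <- as_pair_df(pairs)
  hits <- vapply(bench$motifs, function(m) {
    grepl(m, bench$sequences, fixed = TRUE)
  }, logical(length(bench$sequences)))
  rownames(hits) <- names(bench$sequences)
  vapply(seq_len(nrow(df)), function(i) {
    sum(hits[df$id_a[i], ] & hits[df$id_b[i], ])
  }, 0)
}
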