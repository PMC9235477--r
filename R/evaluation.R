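# Evaluation protocols for imbalanced link prediction: AUPR / AUROC /
# FPR at fixed recall, degree- and distance-stratified breakdowns, hub-edge
# filtering and the spanning-tree-protected sparsification benchmark.
#
# Ties are handled deterministically: scores are grouped by value and each
# threshold group enters the confusion counts together. AUPR uses the
# step-wise (non-interpolated) precision-recall summation; interpolation
# conventions change AUPR in the third decimal, so the choice is fixed and
# documented here.

check_binary <- function(labels, scores) {
  assert_that(length(labels) == length(scores) && length(labels) > 0,
              "labels and scores must be aligned and non-empty")
  assert_that(all(labels %in% c(0, 1)), "labels must be 0/1")
  assert_that(any(labels == 1) && any(labels == 0),
              "both classes must be present")
  assert_that(all(is.finite(scores)), "scores must be finite")
}

# Cumulative TP/FP after each descending threshold group.
threshold_groups <- function(labels, scores) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(1 - l)
  last <- which(!duplicated(grp, fromLast = TRUE))
  list(tp = tp[last], fp = fp[last],
       n_pos = sum(labels == 1), n_neg = sum(labels == 0))
}

#' Area under the precision-recall curve
#'
#' Step-wise summation over descending score thresholds with tie groups:
#' AUPR = sum over groups of (recall_i - recall_(i-1)) * precision_i.
#' For random scores the expectation equals the class prevalence (0.091 at
#' a 1:10 positive:negative ratio).
#'
#' @param labels 0/1 vector
#' @param scores numeric vector, higher = more likely positive
#' @export
aupr <- function(labels, scores) {
  check_binary(labels, scores)
  g <- threshold_groups(labels, scores)
  recall <- g$tp / g$n_pos
  precision <- g$tp / (g$tp + g$fp)
  drec <- diff(c(0, recall))
  sum(drec * precision)
}

#' Area under the ROC curve
#'
#' Trapezoidal area, equal to the Mann-Whitney concordance probability
#' (ties counted 1/2).
#' @inheritParams aupr
#' @export
auroc <- function(labels, scores) {
  check_binary(labels, scores)
  r <- rank(scores, ties.method = "average")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' False positive rate at a recall level
#'
#' FPR at the smallest (i.e. most permissive last) descending-threshold
#' group achieving recall >= `recall_level`; tied scores enter together, so
#' a degenerate all-equal score vector yields FPR 1 at any achievable
#' recall.
#'
#' @inheritParams aupr
#' @param recall_level target recall in (0, 1]
#' @export
fpr_at_recall <- function(labels, scores, recall_level) {
  check_binary(labels, scores)
  assert_that(recall_level > 0 && recall_level <= 1,
              "recall_level must be in (0, 1]")
  g <- threshold_groups(labels, scores)
  recall <- g$tp / g$n_pos
  i <- which(recall >= recall_level)
  assert_that(length(i) > 0, sprintf("recall %g is unreachable", recall_level))
  g$fp[i[1]] / g$n_neg
}

#' Stratify pairs by maximum endpoint degree
#'
#' Groups each pair by M = max(degree(p), degree(q)) in the reference
#' network, default bins 2-5, 6-10, 11-20, >=21; pairs with M < 2 land in
#' an underflow stratum "<2". All endpoints must be in the network.
#'
#' @param pairs pair container
#' @param net a `ppi_network`
#' @param bin_edges increasing integer lower edges of the bins
#' @return named list of pair data.frames (strata partition the input)
#' @export
stratify_by_max_degree <- function(pairs, net, bin_edges = c(2, 6, 11, 21)) {
  df <- as_pair_df(pairs)
  nodes <- network_nodes(net)
  off <- setdiff(unique(c(df$id_a, df$id_b)), nodes)
  assert_that(length(off) == 0L,
              sprintf("protein '%s' is not in the network",
                      if (length(off)) off[1] else ""))
  deg <- network_degree(net)
  M <- pmax(deg[df$id_a], deg[df$id_b])
  labels_bins <- c(sprintf("<%d", bin_edges[1]),
                   if (length(bin_edges) > 1)
                     sprintf("%d-%d", bin_edges[-length(bin_edges)],
                             bin_edges[-1] - 1),
                   sprintf(">=%d", bin_edges[length(bin_edges)]))
  cut_idx <- findInterval(M, bin_edges) + 1L
  strata <- split(seq_len(nrow(df)), factor(labels_bins[cut_idx],
                                            levels = labels_bins))
  out <- lapply(strata, function(i) {
    x <- df[i, , drop = FALSE]; rownames(x) <- NULL; x
  })
  out[vapply(out, nrow, 0L) > 0]
}

#' Stratify pairs by shortest-path distance
#'
#' Unweighted shortest-path distance in the reference network; pairs in
#' different components go to the "Inf" stratum.
#' @param pairs pair container
#' @param net a `ppi_network`
#' @export
stratify_by_distance <- function(pairs, net) {
  df <- as_pair_df(pairs)
  nodes <- network_nodes(net)
  off <- setdiff(unique(c(df$id_a, df$id_b)), nodes)
  assert_that(length(off) == 0L,
              sprintf("protein '%s' is not in the network",
                      if (length(off)) off[1] else ""))
  dmat <- igraph::distances(net$g, v = unique(df$id_a),
                            to = unique(df$id_b), weights = NA)
  d <- dmat[cbind(df$id_a, df$id_b)]
  lab <- ifelse(is.infinite(d), "Inf", as.character(d))
  strata <- split(seq_len(nrow(df)), lab)
  lapply(strata, function(i) {
    x <- df[i, , drop = FALSE]; rownames(x) <- NULL; x
  })
}

#' Remove pairs incident on hub proteins
#'
#' Drops any pair where either endpoint has degree >= `cutoff` (default 21)
#' in the reference network; the boundary is strict, so degrees (20, 20)
#' are kept.
#' @param pairs pair container
#' @param net a `ppi_network`
#' @param cutoff hub degree cutoff
#' @export
filter_hub_edges <- function(pairs, net, cutoff = 21) {
  df <- as_pair_df(pairs)
  deg <- network_degree(net)
  assert_that(all(c(df$id_a, df$id_b) %in% names(deg)),
              "all endpoints must be in the network")
  keep <- deg[df$id_a] < cutoff & deg[df$id_b] < cutoff
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spanning-tree-protected network sparsification
#'
#' Keeps round(p * |E|) edges (round half up): a seeded random spanning tree
#' is fully retained to guarantee connectivity, and the remaining kept edges
#' are sampled uniformly from the non-tree edges. The removed edges form the
#' held-out positive set E \ E_p.
#'
#' The random spanning tree is obtained by minimum spanning tree over seeded
#' i.i.d. uniform edge weights (randomised Kruskal); uniformity over all
#' spanning trees is not required and the construction is recorded in the
#' split metadata.
#'
#' @param net a connected `ppi_network`
#' @param p fraction of edges to keep, in (0, 1]
#' @param seed integer seed
#' @return a `sparsified_split`: list(p, net, held_out, seed, counts,
#'   method)
#' @export
sparsify <- function(net, p, seed = 1) {
  assert_that(p > 0 && p <= 1, "p must be in (0, 1]")
  comps <- igraph::components(net$g)
  assert_that(comps$no == 1L, "network must be connected")
  ne <- igraph::ecount(net$g)
  nv <- igraph::vcount(net$g)
  target <- floor(p * ne + 0.5)
  assert_that(target >= nv - 1L,
              sprintf(paste("p = %g keeps %d edges but a spanning tree needs",
                            "%d; the feasible minimum p is %.4f"),
                      p, target, nv - 1L, (nv - 1L) / ne))
  kept_idx <- withr::with_seed(seed, {
    rw <- runif(ne)
    tree <- igraph::mst(net$g, weights = rw)
    tree_ids <- igraph::get_edge_ids(net$g, t(igraph::as_edgelist(tree)))
    extra <- setdiff(seq_len(ne), tree_ids)
    n_extra <- target - length(tree_ids)
    keep_extra <- if (n_extra > 0) sample(extra, n_extra) else integer()
    sort(c(tree_ids, keep_extra))
  })
  g_p <- igraph::subgraph_from_edges(net$g, kept_idx, delete.vertices = FALSE)
  el <- igraph::as_edgelist(net$g)
  held <- setdiff(seq_len(ne), kept_idx)
  held_df <- data.frame(id_a = el[held, 1], id_b = el[held, 2],
                        stringsAsFactors = FALSE)
  subnet <- structure(list(g = g_p), class = "ppi_network")
  assert_that(igraph::components(g_p)$no == 1L,
              "internal error: sparsified network is disconnected")
  structure(list(p = p, net = subnet, held_out = held_df, seed = seed,
                 counts = c(kept = length(kept_idx), held_out = length(held),
                            nodes = nv),
                 method = "mst-over-seeded-uniform-weights"),
            class = "sparsified_split")
}

#' Build a test set for a sparsified benchmark
#'
#' Positives are exactly the held-out edges E \ E_p; negatives are sampled
#' from (V x V) \ E (non-edges of the *full* network) at `ratio` times the
#' positive count, and split into train/test portions by the same p (the
#' train portion is recorded for comparators that consume it). Both set
#' identities are asserted.
#'
#' @param net the full `ppi_network`
#' @param split a `sparsified_split` of `net`
#' @param ratio negatives per positive (default 10)
#' @param seed integer seed
#' @return list(positives, negatives, negatives_train, labels data.frame)
#' @export
sparsified_testset <- function(net, split, ratio = 10, seed = 1) {
  pos <- split$held_out
  # identity S_p^+ = E \ E_p
  full_keys <- pair_key(network_edges(net)$id_a, network_edges(net)$id_b)
  kept_keys <- pair_key(network_edges(split$net)$id_a,
                        network_edges(split$net)$id_b)
  pos_keys <- pair_key(pos$id_a, pos$id_b)
  assert_that(setequal(pos_keys, setdiff(full_keys, kept_keys)),
              "held-out set identity violated")
  neg <- sample_negatives(network_nodes(net), network_edges(net)[, 1:2],
                          ratio = ratio, seed = seed)
  # negatives must avoid the full edge set
  assert_that(!any(pair_key(neg$id_a, neg$id_b) %in% full_keys),
              "negative sampling produced a true edge")
  scaled <- ratio * nrow(pos)
  neg_test <- neg[seq_len(min(scaled, nrow(neg))), , drop = FALSE]
  neg_train <- neg[-seq_len(nrow(neg_test)), , drop = FALSE]
  labels <- rbind(data.frame(pos, label = 1),
                  data.frame(neg_test, label = 0))
  rownames(labels) <- NULL
  list(positives = pos, negatives = neg_test, negatives_train = neg_train,
       labels = labels)
}

#' Assemble a full evaluation report
#'
#' @param labels 0/1 vector
#' @param scores aligned numeric scores
#' @param recall_levels recall levels for the FPR entries
#' @param strata optional named list mapping stratum label -> index vector
#'   into labels/scores; each stratum gets a sub-report (single-class strata
#'   are reported with NA metrics)
#' @return an `eval_report` list: aupr, auroc, fpr_at (named), n_pos, n_neg,
#'   strata
#' @export
evaluate <- function(labels, scores, recall_levels = c(0.1, 0.5),
                     strata = NULL) {
  check_binary(labels, scores)
  fprs <- vapply(recall_levels, function(r) fpr_at_recall(labels, scores, r),
                 0.0)
  names(fprs) <- sprintf("fpr_at_%g", recall_levels)
  rep <- list(aupr = aupr(labels, scores), auroc = auroc(labels, scores),
              fpr_at = as.list(fprs),
              n_pos = sum(labels == 1), n_neg = sum(labels == 0))
  if (!is.null(strata)) {
    idx_all <- sort(unlist(strata, use.names = FALSE))
    assert_that(identical(idx_all, seq_along(labels)),
                "strata must partition the evaluated pairs")
    rep$strata <- lapply(strata, function(i) {
      if (length(unique(labels[i])) < 2) {
        list(aupr = NA_real_, auroc = NA_real_,
             n_pos = sum(labels[i] == 1), n_neg = sum(labels[i] == 0))
      } else {
        list(aupr = aupr(labels[i], scores[i]),
             auroc = auroc(labels[i], scores[i]),
             n_pos = sum(labels[i] == 1), n_neg = sum(labels[i] == 0))
      }
    })
  }
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: AUPR %.4f, AUROC %.4f (%d+/%d-)>\n",
              x$aupr, x$auroc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Write an evaluation report
#'
#' JSON with metric names `aupr`, `auroc`, `fpr_at_0.1`, ... plus `strata`;
#' optionally also a flat TSV.
#' @param report an `eval_report`
#' @param path JSON output path
#' @param tsv optional TSV output path
#' @export
write_report <- function(report, path, tsv = NULL) {
  flat <- c(list(aupr = report$aupr, auroc = report$auroc),
            report$fpr_at,
            list(n_pos = report$n_pos, n_neg = report$n_neg))
  if (!is.null(report$strata)) flat$strata <- report$strata
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(tsv)) {
    base <- data.frame(metric = c("aupr", "auroc", names(report$fpr_at)),
                       value = unlist(c(report$aupr, report$auroc,
                                        report$fpr_at)))
    write.table(base, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
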