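# GLIDE link scoring: a local common-weighted-neighbour term merged with a
# global diffusion-state proximity.
#
# GLIDE(p,q) = exp(alpha * u/(u + beta)) * CWN(p,q) + u,  u = 1 / DSD_gamma(p,q)
#
# With the defaults alpha = 0.1, beta = 1000 the local CWN term dominates
# whenever the pair shares neighbours, while the global diffusion proximity u
# orders pairs with equal (notably zero) local score.

#' GLIDE scoring parameters
#'
#' @param alpha weight of the global proximity inside the exponential
#'   multiplier of the local term (default 0.1).
#' @param beta damping constant in the multiplier (default 1000). Large beta
#'   keeps the multiplier close to 1, so the local score dominates and the
#'   global term mostly breaks ties.
#' @param gamma damping of the diffusion-walk series; `gamma = 1` is the
#'   un-damped converged diffusion-state construction.
#' @param local_metric tag of the local score; only `"cwn"` is implemented.
#' @export
glide_params <- function(alpha = 0.1, beta = 1000, gamma = 1,
                         local_metric = "cwn") {
  assert_that(is.numeric(alpha) && alpha >= 0, "alpha must be >= 0")
  assert_that(is.numeric(beta) && beta > 0, "beta must be > 0")
  assert_that(is.numeric(gamma) && gamma > 0 && gamma <= 1,
              "gamma must be in (0, 1]")
  assert_that(identical(local_metric, "cwn"),
              "only the 'cwn' local metric is implemented")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 local_metric = local_metric),
            class = "glide_params")
}

#' Common Weighted Normalized (CWN) local score
#'
#' Sum over common neighbours z of (w(p,z) + w(z,q)) / d_w(z), where d_w is
#' the weighted degree. Zero when the pair has no common neighbour; each
#' additional common neighbour strictly increases the score.
#'
#' @param net a `ppi_network`
#' @param p,q distinct protein ids in `net`
#' @export
cwn <- function(net, p, q) {
  check_node(net, p); check_node(net, q)
  assert_that(p != q, "cwn is undefined for self-pairs")
  g <- net$g
  np <- igraph::neighbors(g, p)$name
  nq <- igraph::neighbors(g, q)$name
  common <- intersect(np, nq)
  if (length(common) == 0L) return(0)
  dz <- igraph::strength(g, vids = common, weights = igraph::E(g)$weight)
  wp <- edge_weights_to(net, p, common)
  wq <- edge_weights_to(net, q, common)
  sum((wp + wq) / dz)
}

edge_weights_to <- function(net, p, targets) {
  eids <- igraph::get_edge_ids(net$g, rbind(rep(p, length(targets)), targets))
  igraph::E(net$g)$weight[eids]
}

#' Diffusion states of a connected network
#'
#' Closed-form diffusion states: with P the row-normalised weighted adjacency
#' and W = 1 pi' the projector onto the stationary distribution pi
#' (pi_i proportional to weighted degree), the state matrix is
#' X = (I - gamma (P - W))^{-1}. For gamma = 1 the L1 distance between two
#' rows of X equals the converged limit of the difference of truncated
#' random-walk visit counts, the diffusion state distance (DSD).
#'
#' @param net a connected `ppi_network`
#' @param gamma walk damping in (0, 1]; 1 = un-damped limit.
#' @return object of class `diffusion_states` with the node ordering and the
#'   dense state matrix (one row per node).
#' @export
diffusion_states <- function(net, gamma = 1) {
  comps <- igraph::components(net$g)
  assert_that(comps$no == 1L,
              paste("network is disconnected: compute diffusion states",
                    "per connected component"))
  nodes <- network_nodes(net)
  n <- length(nodes)
  A <- as.matrix(igraph::as_adjacency_matrix(net$g, attr = "weight",
                                             sparse = TRUE))
  d <- rowSums(A)
  assert_that(all(d > 0), "isolated node in a supposedly connected network")
  P <- A / d
  pi_st <- d / sum(d)
  M <- diag(n) - gamma * (P - tcrossprod(rep(1, n), pi_st))
  X <- solve(M)
  dimnames(X) <- list(nodes, nodes)
  structure(list(nodes = nodes, states = X, gamma = gamma),
            class = "diffusion_states")
}

#' Diffusion state distance between two nodes
#'
#' L1 distance between the nodes' diffusion-state rows.
#' @param states a `diffusion_states` object
#' @param p,q protein ids covered by `states`
#' @export
ds_distance <- function(states, p, q) {
  assert_that(p %in% states$nodes && q %in% states$nodes,
              "node not covered by these diffusion states",
              class = "glideppi_key_error")
  sum(abs(states$states[p, ] - states$states[q, ]))
}

#' Global diffusion proximity u(p,q)
#'
#' Reciprocal of the diffusion state distance. Finite and positive for any
#' two distinct nodes of a connected component.
#' @param states a `diffusion_states` object
#' @param p,q distinct protein ids covered by `states`
#' @export
global_proximity <- function(states, p, q) {
  assert_that(p != q, "global proximity is undefined for self-pairs")
  dd <- ds_distance(states, p, q)
  assert_that(dd > 0, sprintf("zero diffusion distance between '%s' and '%s'",
                              p, q))
  1 / dd
}

# Per-component diffusion states, computed lazily and cached.
glide_scorer <- function(net, params = glide_params()) {
  comps <- igraph::components(net$g)
  membership <- comps$membership
  cache <- vector("list", comps$no)
  get_states <- function(cid) {
    if (is.null(cache[[cid]])) {
      vids <- names(membership)[membership == cid]
      sub <- igraph::induced_subgraph(net$g, vids)
      subnet <- structure(list(g = sub), class = "ppi_network")
      cache[[cid]] <<- if (length(vids) >= 2L)
        diffusion_states(subnet, gamma = params$gamma) else NULL
    }
    cache[[cid]]
  }
  list(net = net, params = params, membership = membership,
       get_states = get_states)
}

glide_from_parts <- function(cwn_val, u, params) {
  exp(params$alpha * u / (u + params$beta)) * cwn_val + u
}

#' GLIDE score of a protein pair
#'
#' `exp(alpha * u/(u+beta)) * CWN(p,q) + u`. For a pair in different
#' connected components the diffusion distance is infinite, so u = 0 and the
#' multiplier takes its limit 1: the score falls back to the CWN term alone
#' (which is itself 0 across components).
#'
#' @param net a `ppi_network`
#' @param p,q distinct protein ids in `net`
#' @param params a [glide_params()] object
#' @export
glide <- function(net, p, q, params = glide_params()) {
  check_node(net, p); check_node(net, q)
  assert_that(p != q, "GLIDE is undefined for self-pairs")
  sc <- glide_scorer(net, params)
  glide_pair(sc, p, q)
}

glide_pair <- function(scorer, p, q) {
  params <- scorer$params
  cwn_val <- cwn(scorer$net, p, q)
  cp <- scorer$membership[[p]]; cq <- scorer$membership[[q]]
  u <- if (cp == cq) {
    st <- scorer$get_states(cp)
    global_proximity(st, p, q)
  } else 0
  glide_from_parts(cwn_val, u, params)
}

#' GLIDE scores for a list of pairs
#'
#' Scores every pair on the given network, preserving order. Pairs with an
#' endpoint absent from the network receive score 0 and are flagged
#' (`off_network = TRUE`); graph measures are only defined for in-network
#' proteins.
#'
#' @param net a `ppi_network`
#' @param pairs pair container (data.frame/matrix/list); distinct unordered
#'   pairs, no self-pairs
#' @param params a [glide_params()] object
#' @return a `glide_table`: data.frame with id_a, id_b, score, off_network,
#'   plus provenance attributes.
#' @export
glide_table <- function(net, pairs, params = glide_params()) {
  df <- as_pair_df(pairs)
  assert_that(!any(df$id_a == df$id_b), "self-pairs are not scoreable")
  assert_that(!anyDuplicated(pair_key(df$id_a, df$id_b)),
              "duplicate pairs in input")
  nodes <- network_nodes(net)
  sc <- glide_scorer(net, params)
  n <- nrow(df)
  score <- numeric(n)
  off <- logical(n)
  for (i in seq_len(n)) {
    a <- df$id_a[i]; b <- df$id_b[i]
    if (!(a %in% nodes) || !(b %in% nodes)) {
      score[i] <- 0; off[i] <- TRUE
    } else {
      score[i] <- glide_pair(sc, a, b)
    }
  }
  out <- data.frame(id_a = df$id_a, id_b = df$id_b, score = score,
                    off_network = off, stringsAsFactors = FALSE)
  attr(out, "params") <- params
  attr(out, "network_size") <- network_size(net)
  class(out) <- c("glide_table", "data.frame")
  out
}

#' Percentile threshold on a GLIDE score table
#'
#' Numeric threshold at the g_t-th percentile of the table's scores, by
#' linear interpolation between order statistics (inclusive rule,
#' [stats::quantile()] type 7). Monotone non-decreasing in g_t; the limit
#' g_t -> 100 returns the maximum score.
#'
#' @param table a `glide_table` (or numeric vector of scores)
#' @param g_t percentile in (0, 100); the co-supervision default is 92.5
#' @export
percentile_threshold <- function(table, g_t = 92.5) {
  assert_that(is.numeric(g_t) && length(g_t) == 1L && g_t > 0 && g_t < 100,
              "g_t must be a percentile in (0, 100)")
  scores <- if (is.numeric(table)) table else table$score[!table$off_network]
  assert_that(length(scores) > 0L, "empty score table")
  unname(quantile(scores, g_t / 100, type = 7, names = FALSE))
}
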