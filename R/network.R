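# Undirected weighted protein-protein interaction networks.
#
# A `ppi_network` wraps an igraph object. Edges carry positive weights
# (unit weight when the input has none); self-loops are rejected and
# duplicate records (in either orientation) are collapsed to the first
# occurrence. Isolated proteins may be registered explicitly.

#' Build a PPI network from edge records
#'
#' @param edge_records a data.frame/matrix with columns (protein_a, protein_b
#'   \[, weight\]), or a list of length-2/3 vectors. Missing weights default
#'   to 1.
#' @param nodes optional character vector of isolated proteins to register in
#'   addition to edge endpoints.
#' @return an object of class `ppi_network`.
#' @export
build_network <- function(edge_records, nodes = character()) {
  if (is.data.frame(edge_records) || is.matrix(edge_records)) {
    df <- as.data.frame(edge_records, stringsAsFactors = FALSE)
  } else if (is.list(edge_records)) {
    df <- do.call(rbind, lapply(seq_along(edge_records), function(i) {
      r <- edge_records[[i]]
      assert_that(length(r) %in% c(2L, 3L),
                  sprintf("malformed edge record %d: expected 2 or 3 fields, got %d",
                          i, length(r)))
      data.frame(a = as.character(r[[1]]), b = as.character(r[[2]]),
                 w = if (length(r) == 3L) as.numeric(r[[3]]) else 1,
                 stringsAsFactors = FALSE)
    }))
  } else {
    stop("edge_records must be a data.frame, matrix or list")
  }
  if (is.null(df) || nrow(df) == 0L) {
    df <- data.frame(a = character(), b = character(), w = numeric())
  }
  assert_that(ncol(df) %in% c(2L, 3L), "edge records need 2 or 3 columns")
  if (ncol(df) == 2L) df$w <- 1
  names(df) <- c("a", "b", "w")
  df$a <- as.character(df$a); df$b <- as.character(df$b)
  df$w <- suppressWarnings(as.numeric(df$w))
  bad <- which(is.na(df$a) | is.na(df$b) | !nzchar(df$a) | !nzchar(df$b))
  assert_that(length(bad) == 0L,
              sprintf("malformed edge record at line %d: empty protein id",
                      if (length(bad)) bad[1] else 0L))
  bad_w <- which(is.na(df$w) | df$w <= 0)
  assert_that(length(bad_w) == 0L,
              sprintf("malformed edge record at line %d: weight must be a positive number",
                      if (length(bad_w)) bad_w[1] else 0L))
  loops <- which(df$a == df$b)
  assert_that(length(loops) == 0L,
              sprintf("self-loop rejected at line %d: %s-%s",
                      if (length(loops)) loops[1] else 0L,
                      if (length(loops)) df$a[loops[1]] else "",
                      if (length(loops)) df$b[loops[1]] else ""))
  # undirected dedup: keep the first occurrence of each unordered pair
  keys <- pair_key(df$a, df$b)
  keep <- !duplicated(keys)
  df <- df[keep, , drop = FALSE]
  all_nodes <- unique(c(df$a, df$b, as.character(nodes)))
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = df$a, to = df$b, weight = df$w),
    directed = FALSE, vertices = data.frame(name = all_nodes)
  )
  structure(list(g = g), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network: %d proteins, %d interactions>\n",
              igraph::vcount(x$g), igraph::ecount(x$g)))
  invisible(x)
}

#' Protein identifiers of a network
#' @param net a `ppi_network`
#' @export
network_nodes <- function(net) igraph::V(net$g)$name

#' Edge table of a network
#' @param net a `ppi_network`
#' @return data.frame with columns id_a, id_b, weight
#' @export
network_edges <- function(net) {
  el <- igraph::as_edgelist(net$g, names = TRUE)
  data.frame(id_a = el[, 1], id_b = el[, 2],
             weight = if (igraph::ecount(net$g))
               igraph::E(net$g)$weight else numeric(),
             stringsAsFactors = FALSE)
}

#' Node degrees
#' @param net a `ppi_network`
#' @param weighted if TRUE, sum of incident edge weights (strength);
#'   otherwise edge counts.
#' @export
network_degree <- function(net, weighted = FALSE) {
  if (weighted) igraph::strength(net$g, weights = igraph::E(net$g)$weight)
  else igraph::degree(net$g)
}

#' Number of edges / nodes
#' @param net a `ppi_network`
#' @export
network_size <- function(net) {
  c(nodes = igraph::vcount(net$g), edges = igraph::ecount(net$g))
}

#' Test whether an unordered pair is an edge
#' @param net a `ppi_network`
#' @param a,b protein ids
#' @export
has_edge <- function(net, a, b) {
  if (!all(c(a, b) %in% network_nodes(net))) return(FALSE)
  as.logical(igraph::are_adjacent(net$g, a, b))
}

check_node <- function(net, id) {
  assert_that(id %in% network_nodes(net),
              sprintf("unknown protein '%s': not in the network", id),
              class = "glideppi_key_error")
}
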