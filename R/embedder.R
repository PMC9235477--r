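# Pluggable per-residue sequence embedders.
#
# Production use plugs a pretrained protein-language-model adapter through
# the same interface (a function of one sequence returning an L x d0
# matrix). The shipped deterministic hash-window embedder makes the whole
# pipeline testable offline: the vector of residue i is a seeded
# pseudo-random function of the k-mer window centred on i, so identical
# windows map to identical rows regardless of context.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
AA_PAD <- "-"

#' Deterministic hash-window embedder
#'
#' Each residue is embedded as `tanh` of the sum of per-(window offset,
#' letter) basis vectors drawn once from a seeded normal table. Positions
#' outside the sequence contribute a padding basis vector.
#'
#' @param k odd window width (default 5)
#' @param dim embedding dimension d0 (default 64)
#' @param seed integer seed fixing the basis table
#' @return an object of class `hash_embedder`; call [embed_sequence()] with it.
#' @export
hash_embedder <- function(k = 5, dim = 64, seed = 101) {
  assert_that(k >= 1 && k %% 2 == 1, "window width k must be odd and >= 1")
  assert_that(dim >= 1, "embedding dimension must be >= 1")
  letters_all <- c(AA_ALPHABET, AA_PAD)
  tab <- withr::with_seed(seed, {
    m <- matrix(rnorm(k * length(letters_all) * dim, sd = 1 / sqrt(k)),
                nrow = k * length(letters_all), ncol = dim)
    m
  })
  rownames(tab) <- paste(rep(seq_len(k), each = length(letters_all)),
                         rep(letters_all, k), sep = ":")
  structure(list(k = k, dim = dim, seed = seed, table = tab,
                 tag = sprintf("hash-window-k%d-d%d-s%d", k, dim, seed)),
            class = "hash_embedder")
}

#' Embedder tag
#' @param embedder an embedder object
#' @export
embedder_tag <- function(embedder) embedder$tag

#' Embedding dimension of an embedder
#' @param embedder an embedder object
#' @export
embedder_dim <- function(embedder) embedder$dim

#' Embed an amino-acid sequence
#'
#' @param seq a character scalar over the 20 amino-acid letters plus X
#'   (case-insensitive)
#' @param embedder an embedder object, e.g. [hash_embedder()]
#' @return an L x d0 numeric matrix, deterministic for fixed
#'   (sequence, embedder).
#' @export
embed_sequence <- function(seq, embedder) {
  assert_that(is.character(seq) && length(seq) == 1L && nzchar(seq),
              "sequence must be a non-empty character scalar")
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!(chars %in% AA_ALPHABET))
  assert_that(length(bad) == 0L,
              sprintf("illegal residue '%s' at position %d",
                      if (length(bad)) chars[bad[1]] else "",
                      if (length(bad)) bad[1] else 0L))
  UseMethod("embed_sequence", embedder)
}

#' @export
embed_sequence.default <- function(seq, embedder) {
  stop("no embed_sequence method for this embedder")
}

#' @export
embed_sequence.hash_embedder <- function(seq, embedder) {
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- length(chars)
  k <- embedder$k
  half <- (k - 1L) %/% 2L
  padded <- c(rep(AA_PAD, half), chars, rep(AA_PAD, half))
  out <- matrix(0, nrow = L, ncol = embedder$dim)
  for (o in seq_len(k)) {
    keys <- paste(o, padded[seq_len(L) + (o - 1L)], sep = ":")
    out <- out + embedder$table[keys, , drop = FALSE]
  }
  tanh(out)
}

#' Embed a set of named sequences
#'
#' @param seqs named character vector of sequences
#' @param embedder an embedder object
#' @return named list of L x d0 matrices (an in-memory embedding cache)
#' @export
embed_proteins <- function(seqs, embedder) {
  assert_that(!is.null(names(seqs)) && all(nzchar(names(seqs))),
              "sequences must be named by protein id")
  assert_that(!anyDuplicated(names(seqs)), "duplicate protein ids")
  lapply(setNames(as.list(seqs), names(seqs)), embed_sequence,
         embedder = embedder)
}

#' Save / load an embedding cache
#'
#' The cache is a named list of per-protein embedding matrices keyed by
#' protein id, stored as a single serialized file.
#' @param cache named list of matrices
#' @param path file path
#' @export
save_embedding_cache <- function(cache, path) {
  saveRDS(cache, path)
  invisible(path)
}

#' @rdname save_embedding_cache
#' @export
load_embedding_cache <- function(path) readRDS(path)
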