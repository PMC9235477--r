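# Readers/writers for the plain-text formats the tool touches:
# FASTA (via Biostrings), edge-list TSV (no header, '#' comments),
# pair/example TSV (headered), GLIDE score TSV, benchmark bundles.

#' Read a FASTA file of protein sequences
#'
#' Ids are the header up to the first whitespace; sequences are uppercased.
#' Wrapped and unwrapped records are equivalent.
#' @param path FASTA file
#' @return named character vector id -> sequence
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  assert_that(!anyDuplicated(ids),
              sprintf("duplicate FASTA id '%s'",
                      ids[duplicated(ids)][1]))
  seqs <- toupper(as.character(set))
  empty <- which(!nzchar(seqs))
  assert_that(length(empty) == 0L,
              sprintf("empty sequence for id '%s'",
                      if (length(empty)) ids[empty[1]] else ""))
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#' @param seqs named character vector
#' @param path output path
#' @param width line wrap width
#' @export
write_fasta <- function(seqs, path, width = 60) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read an edge-list TSV
#'
#' Columns `protein_a<TAB>protein_b[<TAB>weight]`, no header, comment lines
#' starting with '#', UTF-8. Malformed lines raise errors naming the line.
#' @param path TSV file
#' @return a `ppi_network` (via [build_network()])
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  recs <- lapply(keep, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    assert_that(length(f) %in% c(2L, 3L),
                sprintf("parse error at line %d: expected 2 or 3 tab-separated fields, got %d",
                        i, length(f)))
    if (length(f) == 3L) {
      w <- suppressWarnings(as.numeric(f[3]))
      assert_that(!is.na(w),
                  sprintf("parse error at line %d: weight '%s' is not numeric",
                          i, f[3]))
      list(f[1], f[2], w)
    } else list(f[1], f[2], 1)
  })
  build_network(recs)
}

#' Write a network as an edge-list TSV
#' @param net a `ppi_network`
#' @param path output path
#' @export
write_edge_list <- function(net, path) {
  ed <- network_edges(net)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%s\t%s\t%g", ed$id_a, ed$id_b, ed$weight), con)
  invisible(path)
}

#' Read a pair/example TSV
#'
#' Headered TSV `id_a<TAB>id_b[<TAB>label]`; labels, when present, must be
#' 0/1. Order is preserved; a header-only file yields an empty table.
#' @param path TSV file
#' @return data.frame id_a, id_b \[, label\]
#' @export
read_pairs <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = "character", quote = "",
                   comment.char = "")
  assert_that(ncol(df) >= 2,
              "pair file needs at least columns id_a, id_b")
  names(df)[1:2] <- c("id_a", "id_b")
  if (ncol(df) >= 3 && names(df)[3] == "label") {
    lab <- suppressWarnings(as.numeric(df$label))
    bad <- which(is.na(lab) | !(lab %in% c(0, 1)))
    assert_that(length(bad) == 0L,
                sprintf("bad label '%s' at line %d (labels must be 0/1)",
                        if (length(bad)) df$label[bad[1]] else "",
                        if (length(bad)) bad[1] + 1L else 0L))
    df$label <- lab
  }
  df
}

#' Write a pair/example TSV
#' @param pairs data.frame with id_a, id_b and optional further columns
#' @param path output path
#' @export
write_pairs <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a GLIDE score table
#'
#' TSV `protein_a<TAB>protein_b<TAB>glide_score` with 6 decimal places.
#' @param table a `glide_table`
#' @param path output path
#' @export
write_glide_table <- function(table, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("protein_a\tprotein_b\tglide_score", con)
  writeLines(sprintf("%s\t%s\t%.6f", table$id_a, table$id_b, table$score),
             con)
  invisible(path)
}

#' Read a GLIDE score table written by [write_glide_table()]
#' @param path TSV file
#' @export
read_glide_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "character", "numeric"))
  names(df) <- c("id_a", "id_b", "score")
  df$off_network <- FALSE
  df
}

#' Write a synthetic benchmark bundle
#'
#' Directory with the network edge list, sequences FASTA, train/val/test
#' pair TSVs and a JSON manifest (config, seed, counts) sufficient to
#' re-create the benchmark from the seed.
#' @param bench a `synthetic_benchmark`
#' @param dir output directory (created if needed)
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_list(bench$network, file.path(dir, "network.tsv"))
  write_fasta(bench$sequences, file.path(dir, "sequences.fasta"))
  for (part in c("train", "val", "test")) {
    write_pairs(bench[[part]], file.path(dir, paste0(part, ".tsv")))
  }
  manifest <- list(
    config = bench$config, seed = bench$seed,
    counts = list(
      nodes = unname(network_size(bench$network)["nodes"]),
      edges = unname(network_size(bench$network)["edges"]),
      train = nrow(bench$train), val = nrow(bench$val),
      test = nrow(bench$test), planted = nrow(bench$planted)),
    motifs = as.list(setNames(bench$motifs,
                              seq_along(bench$motifs))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
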