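# Internal helpers shared across modules.

#' @importFrom stats quantile rnorm runif glm binomial coef setNames
#' @importFrom utils read.table write.table modifyList
NULL

# Canonical unordered-pair key "a||b" with a <= b lexicographically.
pair_key <- function(a, b) {
  lo <- ifelse(a <= b, a, b)
  hi <- ifelse(a <= b, b, a)
  paste(lo, hi, sep = "\r")
}

# Map linear indices in 1..choose(n,2) to unordered index pairs (i < j).
# Used for uniform pair sampling without materialising all pairs.
index_to_pair <- function(idx, n) {
  # i is the smallest integer with cumulative count >= idx, where row i
  # (1-based) contributes n - i pairs.
  idx <- as.numeric(idx)
  nn <- as.numeric(n)
  # cumulative pairs before row i: (i-1)*nn - i*(i-1)/2
  i <- floor((2 * nn - 1 - sqrt((2 * nn - 1)^2 - 8 * idx)) / 2) + 1
  # guard against floating-point boundary errors
  before <- (i - 1) * nn - i * (i - 1) / 2
  too_big <- before >= idx
  i[too_big] <- i[too_big] - 1
  before <- (i - 1) * nn - i * (i - 1) / 2
  j <- idx - before + i
  cbind(as.integer(i), as.integer(j))
}

assert_that <- function(ok, msg, class = "glideppi_validation_error") {
  if (!isTRUE(ok)) {
    stop(structure(
      class = c(class, "error", "condition"),
      list(message = msg, call = sys.call(-1))
    ))
  }
  invisible(TRUE)
}

# Normalise a pair container (2-col matrix / data.frame / list of length-2)
# to a character data.frame with columns id_a, id_b.
as_pair_df <- function(pairs) {
  if (is.data.frame(pairs)) {
    assert_that(ncol(pairs) >= 2, "pair table needs at least two columns")
    out <- data.frame(id_a = as.character(pairs[[1]]),
                      id_b = as.character(pairs[[2]]),
                      stringsAsFactors = FALSE)
  } else if (is.matrix(pairs)) {
    out <- data.frame(id_a = as.character(pairs[, 1]),
                      id_b = as.character(pairs[, 2]),
                      stringsAsFactors = FALSE)
  } else if (is.list(pairs)) {
    out <- data.frame(id_a = vapply(pairs, function(p) as.character(p[[1]]), ""),
                      id_b = vapply(pairs, function(p) as.character(p[[2]]), ""),
                      stringsAsFactors = FALSE)
  } else {
    stop("unsupported pair container")
  }
  out
}
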