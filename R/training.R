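# Training-set assembly and the end-to-end training loop.
#
# Negative examples are sampled at a configurable negative:positive ratio
# (default 10:1, matching the strong class imbalance of real interaction
# data). Before training, every example is given a binarised GLIDE target
# computed on the network defined by the positive training examples; the
# targets feed the co-supervision term of the loss.

#' Training configuration
#'
#' @param batch_size pairs per optimizer step (default 25)
#' @param lr Adam learning rate (default 0.001)
#' @param optimizer optimizer tag; only "adam" is implemented
#' @param epochs training epochs (default 10)
#' @param negative_ratio negatives per positive in assembled datasets
#'   (default 10)
#' @param seed integer seed controlling initialization, shuffling and any
#'   dropout
#' @export
train_config <- function(batch_size = 25, lr = 0.001, optimizer = "adam",
                         epochs = 10, negative_ratio = 10, seed = 1) {
  assert_that(batch_size >= 1 && epochs >= 1, "batch_size/epochs must be >= 1")
  assert_that(negative_ratio >= 1, "negative_ratio must be >= 1")
  assert_that(identical(optimizer, "adam"), "only the adam optimizer is implemented")
  assert_that(lr > 0, "learning rate must be positive")
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 optimizer = optimizer, epochs = as.integer(epochs),
                 negative_ratio = as.integer(negative_ratio),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Sample random negative pairs
#'
#' Draws `ratio * |positives|` distinct unordered protein pairs, disjoint
#' from the positives, with no self-pairs; reproducible under `seed`.
#'
#' @param proteins character vector of candidate protein ids
#' @param positives pair container of positive pairs
#' @param ratio negatives per positive
#' @param seed integer seed
#' @return data.frame id_a, id_b
#' @export
sample_negatives <- function(proteins, positives, ratio = 10, seed = 1) {
  proteins <- unique(as.character(proteins))
  n <- length(proteins)
  pos <- as_pair_df(positives)
  pos_keys <- unique(pair_key(pos$id_a, pos$id_b))
  want <- ratio * nrow(pos)
  total <- n * (n - 1) / 2
  feasible <- total - length(pos_keys)
  assert_that(want <= feasible,
              sprintf("negative pool exhausted: requested %d but only %d non-positive pairs exist",
                      want, feasible))
  withr::with_seed(seed, {
    chosen <- character(0)
    out_i <- integer(0); out_j <- integer(0)
    while (length(out_i) < want) {
      k <- max(2 * (want - length(out_i)), 100L)
      idx <- unique(ceiling(runif(k) * total))
      ij <- index_to_pair(idx, n)
      a <- proteins[ij[, 1]]; b <- proteins[ij[, 2]]
      keys <- pair_key(a, b)
      ok <- !(keys %in% pos_keys) & !(keys %in% chosen) & !duplicated(keys)
      take <- which(ok)
      if (length(take) > want - length(out_i))
        take <- take[seq_len(want - length(out_i))]
      chosen <- c(chosen, keys[take])
      out_i <- c(out_i, ij[take, 1]); out_j <- c(out_j, ij[take, 2])
    }
    data.frame(id_a = proteins[out_i], id_b = proteins[out_j],
               stringsAsFactors = FALSE)
  })
}

#' Sample negatives restricted to low GLIDE scores
#'
#' Draws `n` pairs whose GLIDE score lies below the given percentile cutoff
#' of the scored candidate distribution. Only in-network pairs are eligible
#' (graph scores are undefined off-network); a cutoff of 100 reduces to a
#' plain random sample of the in-network candidates.
#'
#' @param candidates pair container of candidate negative pairs
#' @param table a `glide_table` scoring the candidates
#' @param cutoff_percentile percentile in (0, 100\]
#' @param n number of pairs to draw
#' @param seed integer seed
#' @export
sample_negatives_low_glide <- function(candidates, table, cutoff_percentile,
                                       n, seed = 1) {
  assert_that(cutoff_percentile > 0 && cutoff_percentile <= 100,
              "cutoff_percentile must be in (0, 100]")
  cand <- as_pair_df(candidates)
  keys <- pair_key(cand$id_a, cand$id_b)
  tkeys <- pair_key(table$id_a, table$id_b)
  idx <- match(keys, tkeys)
  assert_that(!anyNA(idx), "all candidates must be scored in the table")
  score <- table$score[idx]
  in_net <- !table$off_network[idx]
  if (cutoff_percentile == 100) {
    eligible <- which(in_net)
  } else {
    cutoff <- unname(quantile(table$score[!table$off_network],
                              cutoff_percentile / 100, type = 7))
    eligible <- which(in_net & score < cutoff)
  }
  assert_that(length(eligible) >= n,
              sprintf("only %d eligible low-GLIDE candidates for a request of %d",
                      length(eligible), n))
  pick <- withr::with_seed(seed, sample(eligible, n))
  out <- cand[pick, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach binarised GLIDE targets to training examples
#'
#' Builds the scoring network from the positive training pairs, scores every
#' negative example on it, converts the g_t percentile of the score
#' distribution into a numeric threshold and binarises. Positive examples
#' get target 1 without scoring (each is an edge of the scoring network).
#' Negatives with an endpoint off the network are unscoreable: their target
#' is NA and they are excluded from the co-supervision loss.
#'
#' @param train_positives pair container of positive training pairs (defines
#'   the scoring network)
#' @param examples data.frame id_a, id_b, label (0/1)
#' @param params a [glide_params()]
#' @param g_t binarisation percentile in (0, 100)
#' @param percentile_population "negatives" (default: threshold computed on
#'   the scored negative examples) or "all" (all scored examples)
#' @return `examples` with glide_score, glide_target columns; attributes
#'   record the threshold and the number of unscoreable pairs.
#' @export
make_glide_targets <- function(train_positives, examples,
                               params = glide_params(), g_t = 92.5,
                               percentile_population = c("negatives", "all")) {
  percentile_population <- match.arg(percentile_population)
  pos <- as_pair_df(train_positives)
  assert_that(nrow(pos) > 0, "empty positive set: no network to score on")
  assert_that(all(examples$label %in% c(0, 1)), "labels must be 0/1")
  net <- build_network(data.frame(a = pos$id_a, b = pos$id_b, w = 1))
  ex <- examples
  neg_idx <- which(ex$label == 0)
  ex$glide_score <- NA_real_
  ex$glide_target <- NA_real_
  if (length(neg_idx)) {
    tab <- glide_table(net, ex[neg_idx, c("id_a", "id_b")], params)
    ex$glide_score[neg_idx] <- ifelse(tab$off_network, NA_real_, tab$score)
  }
  pos_idx <- which(ex$label == 1)
  ex$glide_target[pos_idx] <- 1
  scored_neg <- neg_idx[!is.na(ex$glide_score[neg_idx])]
  thr <- NA_real_
  if (length(scored_neg)) {
    pool <- if (percentile_population == "negatives") {
      ex$glide_score[scored_neg]
    } else {
      # score positives too for the pooled distribution
      ptab <- glide_table(net, ex[pos_idx, c("id_a", "id_b")], params)
      c(ex$glide_score[scored_neg], ptab$score[!ptab$off_network])
    }
    thr <- unname(quantile(pool, g_t / 100, type = 7))
    ex$glide_target[scored_neg] <-
      as.numeric(ex$glide_score[scored_neg] >= thr)
  }
  attr(ex, "glide_threshold") <- thr
  attr(ex, "n_unscoreable") <- sum(ex$label == 0 & is.na(ex$glide_score))
  ex
}

adam_init <- function(params) {
  list(m = params_map(params, function(x) x * 0),
       v = params_map(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- params_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- params_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  upd <- params_map2(state$m, state$v, function(m, v)
    lr * (m / bc1) / (sqrt(v / bc2) + eps))
  list(params = params_map2(params, upd, function(p, u) p - u),
       state = state)
}

#' Train the interaction model
#'
#' End-to-end seeded training from fresh initialization: per-batch mean of
#' the multi-objective loss, Adam updates, per-epoch history of the mean
#' training loss and (when a validation set is supplied) validation AUPR.
#'
#' @param model a [seq_model()] (its weights are the seeded starting point)
#' @param examples data.frame id_a, id_b, label, glide_target (from
#'   [make_glide_targets()]; glide_target may be NA)
#' @param embeddings named list of embedding matrices covering every id
#' @param loss_cfg a [loss_config()]
#' @param train_cfg a [train_config()]
#' @param validation optional data.frame id_a, id_b, label for per-epoch AUPR
#' @return list with `model` (trained), `history` (data.frame epoch, loss,
#'   val_aupr), `best_epoch`, `skipped_glide_pairs`, and the resolved configs.
#' @export
train_model <- function(model, examples, embeddings,
                        loss_cfg = loss_config(),
                        train_cfg = train_config(),
                        validation = NULL) {
  ids <- unique(c(examples$id_a, examples$id_b,
                  if (!is.null(validation)) c(validation$id_a, validation$id_b)))
  missing <- setdiff(ids, names(embeddings))
  assert_that(length(missing) == 0L,
              sprintf("missing embedding for protein '%s'",
                      if (length(missing)) missing[1] else ""))
  assert_that("glide_target" %in% names(examples) || loss_cfg$g_p == 0,
              "examples need glide_target columns (see make_glide_targets)")
  if (!"glide_target" %in% names(examples)) examples$glide_target <- NA_real_
  n_ex <- nrow(examples)
  skipped <- sum(is.na(examples$glide_target))
  p <- model$params
  st <- adam_init(p)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_aupr = numeric())
  drop_rate <- model$config$dropout
  withr::with_seed(train_cfg$seed, {
    for (epoch in seq_len(train_cfg$epochs)) {
      ord <- sample.int(n_ex)
      total <- 0
      starts <- seq(1, n_ex, by = train_cfg$batch_size)
      for (s in starts) {
        batch <- ord[s:min(s + train_cfg$batch_size - 1L, n_ex)]
        grads <- NULL
        batch_loss <- 0
        for (b in batch) {
          e1 <- embeddings[[examples$id_a[b]]]
          e2 <- embeddings[[examples$id_b[b]]]
          if (drop_rate > 0) {
            e1 <- e1 * (matrix(runif(length(e1)) >= drop_rate,
                               nrow(e1)) / (1 - drop_rate))
            e2 <- e2 * (matrix(runif(length(e2)) >= drop_rate,
                               nrow(e2)) / (1 - drop_rate))
          }
          fwd <- cpp_model_forward(e1, e2, p$Wp, p$bp, p$Wq, p$bq, p$K,
                                   p$bk, p$gammah, p$kact,
                                   model$config$pool_width)
          lab <- examples$label[b]
          gt <- examples$glide_target[b]
          mag <- mean(fwd$C)
          batch_loss <- batch_loss +
            total_loss(fwd$yhat, lab, gt, mag, loss_cfg)
          scale <- 1 / length(batch)
          dy <- loss_dyhat(fwd$yhat, lab, gt, loss_cfg) * scale
          dC_extra <- matrix((1 - loss_cfg$lambda) * scale /
                               length(fwd$C),
                             nrow(fwd$C), ncol(fwd$C))
          g <- cpp_model_backward(fwd, e1, e2, p$Wp, p$Wq, p$K,
                                  p$gammah, p$kact, dy, dC_extra,
                                  model$config$pool_width)
          g$K <- array(g$K, dim(p$K))
          g$bp <- as.numeric(g$bp); g$bq <- as.numeric(g$bq)
          grads <- if (is.null(grads)) g else params_map2(grads, g, `+`)
        }
        upd <- adam_step(p, grads, st, train_cfg$lr)
        p <- upd$params; st <- upd$state
        total <- total + batch_loss
      }
      mean_loss <- total / n_ex
      val_aupr <- NA_real_
      if (!is.null(validation)) {
        model$params <- p
        preds <- predict_pairs(model, validation, embeddings)
        val_aupr <- aupr(validation$label, preds$score)
      }
      history <- rbind(history,
                       data.frame(epoch = epoch, loss = mean_loss,
                                  val_aupr = val_aupr))
    }
  })
  model$params <- p
  best_epoch <- if (all(is.na(history$val_aupr))) nrow(history)
                else which.max(history$val_aupr)
  list(model = model, history = history, best_epoch = best_epoch,
       skipped_glide_pairs = skipped,
       loss_config = loss_cfg, train_config = train_cfg)
}

#' Predict interaction probabilities for a table of pairs
#'
#' @param model a trained or fresh [seq_model()]
#' @param pairs data.frame id_a, id_b
#' @param embeddings named list of embedding matrices
#' @param contact_maps if TRUE, also return the list of contact maps
#' @return data.frame id_a, id_b, score (plus `contact_maps` attribute when
#'   requested)
#' @export
predict_pairs <- function(model, pairs, embeddings, contact_maps = FALSE) {
  df <- as_pair_df(pairs)
  missing <- setdiff(unique(c(df$id_a, df$id_b)), names(embeddings))
  assert_that(length(missing) == 0L,
              sprintf("missing embedding for protein '%s'",
                      if (length(missing)) missing[1] else ""))
  score <- numeric(nrow(df))
  maps <- if (contact_maps) vector("list", nrow(df)) else NULL
  for (i in seq_len(nrow(df))) {
    pred <- predict_interaction(model, embeddings[[df$id_a[i]]],
                                embeddings[[df$id_b[i]]])
    score[i] <- pred$prob
    if (contact_maps) maps[[i]] <- pred$contact_map
  }
  out <- data.frame(id_a = df$id_a, id_b = df$id_b, score = score,
                    stringsAsFactors = FALSE)
  if (contact_maps) attr(out, "contact_maps") <- maps
  out
}
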