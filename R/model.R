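# Sequence-based interaction model.
#
# Architecture (following the D-SCRIPT reference design): per-residue
# embeddings are projected to d dimensions (affine + ReLU, optional
# dropout), combined residue-by-residue into pairwise features
# (absolute difference and elementwise product), mapped to h hidden
# channels (affine + ReLU), convolved with a (2w+1)^2 kernel and squashed
# by a sigmoid into the full n x m contact map. The interaction head
# max-pools the map with width l, sparsifies it by thresholding at
# mean + gamma_h * var, averages the surviving cells and squashes through
# a sharp trainable logistic:
#   Q = relu(P - mean(P) - gamma_h * var(P))
#   yhat = sigmoid(k_act * (sum(Q) / (#active + 1) - 0.5)).
# All outputs are sigmoid-bounded, so yhat and every contact-map entry lie
# in [0, 1] for arbitrary real-valued inputs.

#' Model configuration
#'
#' Defaults are the reference hyperparameters: projection dimension d = 100,
#' hidden dimension h = 50, convolutional filter width 2w+1 = 7, local
#' max-pooling width l = 9.
#'
#' @param projection_dim d, the projected per-residue dimension
#' @param hidden_dim h, the number of pairwise hidden channels
#' @param conv_width odd width of the square convolution filter
#' @param pool_width l, width (= stride) of the local max pooling
#' @param dropout dropout rate on the projection during training (default 0,
#'   keeping fixed-seed runs bit-stable)
#' @param embedder_tag tag of the embedder the model expects
#' @param seed integer seed for weight initialization
#' @export
model_config <- function(projection_dim = 100, hidden_dim = 50,
                         conv_width = 7, pool_width = 9, dropout = 0,
                         embedder_tag = "hash-window-k5-d64-s101",
                         seed = 1) {
  assert_that(projection_dim >= 1 && hidden_dim >= 1 && pool_width >= 1,
              "dimensions must be positive integers")
  assert_that(conv_width >= 1 && conv_width %% 2 == 1,
              "conv_width must be odd")
  assert_that(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  structure(list(projection_dim = as.integer(projection_dim),
                 hidden_dim = as.integer(hidden_dim),
                 conv_width = as.integer(conv_width),
                 pool_width = as.integer(pool_width),
                 dropout = dropout,
                 embedder_tag = embedder_tag,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Initialize an interaction model
#'
#' Weights are drawn from seeded scaled-normal distributions
#' (sd = sqrt(2 / fan_in)); the contract is seeded reproducibility, so the
#' same (config, embed_dim) always yields bit-identical weights.
#'
#' @param config a [model_config()]
#' @param embed_dim d0, the per-residue dimension of the embedder output
#' @export
seq_model <- function(config = model_config(), embed_dim = 64) {
  d0 <- as.integer(embed_dim)
  d <- config$projection_dim; h <- config$hidden_dim
  k <- config$conv_width
  params <- withr::with_seed(config$seed, list(
    Wp = matrix(rnorm(d0 * d, sd = sqrt(2 / d0)), d0, d),
    bp = numeric(d),
    Wq = matrix(rnorm(2 * d * h, sd = sqrt(2 / (2 * d))), 2 * d, h),
    bq = numeric(h),
    K = array(rnorm(k * k * h, sd = sqrt(2 / (k * k * h))), c(k, k, h)),
    bk = 0,
    gammah = 0, kact = 20
  ))
  structure(list(config = config, embed_dim = d0, params = params),
            class = "seq_model")
}

#' @export
print.seq_model <- function(x, ...) {
  cat(sprintf(paste0("<seq_model: d0=%d -> d=%d, h=%d channels, ",
                     "%dx%d conv, pool %d>\n"),
              x$embed_dim, x$config$projection_dim, x$config$hidden_dim,
              x$config$conv_width, x$config$conv_width,
              x$config$pool_width))
  invisible(x)
}

check_embedding <- function(e, model, arg) {
  assert_that(is.matrix(e) && is.numeric(e) && nrow(e) >= 1,
              sprintf("%s must be an L x d0 numeric matrix", arg))
  assert_that(ncol(e) == model$embed_dim,
              sprintf("embedder dimension %d does not match model d0 = %d",
                      ncol(e), model$embed_dim),
              class = "glideppi_config_error")
}

model_forward <- function(model, e1, e2) {
  check_embedding(e1, model, "e1"); check_embedding(e2, model, "e2")
  p <- model$params
  cpp_model_forward(e1, e2, p$Wp, p$bp, p$Wq, p$bq, p$K, p$bk,
                    p$gammah, p$kact, model$config$pool_width)
}

#' Predict interaction for a pair of embedded sequences
#'
#' @param model a [seq_model()]
#' @param e1,e2 embedding matrices from the model's embedder
#'   (n x d0 and m x d0)
#' @return an `interaction_prediction`: probability `prob` in \[0,1\] and the
#'   full-resolution `contact_map` (n x m, entries in \[0,1\]); metadata
#'   records the 1-based residue-index convention and the pooled-map shape.
#' @export
predict_interaction <- function(model, e1, e2) {
  fwd <- model_forward(model, e1, e2)
  structure(list(prob = fwd$yhat,
                 contact_map = fwd$C,
                 metadata = list(
                   shape = dim(fwd$C),
                   pooled_shape = dim(fwd$P),
                   index_base = 1L,
                   coordinate_convention = paste(
                     "contact_map[i, j] = predicted contact probability",
                     "between residue i of the first and residue j of the",
                     "second protein (1-based, full resolution; pooling is",
                     "internal to the interaction head)"))),
            class = "interaction_prediction")
}

#' Contact-map magnitude
#'
#' Mean of the predicted contact-map entries; the L_MAG regularizer of the
#' training loss. Zero iff the map is identically zero, and scale-free in
#' the sequence lengths.
#'
#' @param pred an `interaction_prediction` (or a contact-map matrix)
#' @export
contact_magnitude <- function(pred) {
  cm <- if (inherits(pred, "interaction_prediction")) pred$contact_map
        else pred
  assert_that(is.matrix(cm) && is.numeric(cm), "invalid contact map")
  mean(cm)
}

#' Save / load a model checkpoint
#'
#' Single-file serialized weights plus model config, embedder tag and seed;
#' optional extra metadata (e.g. resolved training configs) travels with it.
#' @param model a `seq_model`
#' @param path file path
#' @param extra optional named list stored alongside
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  saveRDS(list(model = model, extra = extra,
               package_version = as.character(utils::packageVersion("glideppi"))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  assert_that(inherits(obj$model, "seq_model"), "not a model checkpoint")
  obj
}

# Parameter-list arithmetic helpers for the optimizer.
params_map2 <- function(a, b, f) {
  out <- a
  for (nm in names(a)) out[[nm]] <- f(a[[nm]], b[[nm]])
  out
}
params_map <- function(a, f) {
  out <- a
  for (nm in names(a)) out[[nm]] <- f(a[[nm]])
  out
}
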