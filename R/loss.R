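# Multi-objective training loss:
#
#   L = lambda * (L_BCE + g_p * L_GLIDE) + (1 - lambda) * L_MAG
#
# L_BCE is binary cross-entropy against the interaction label, L_GLIDE is
# BCE against the percentile-binarised GLIDE score of the pair, and L_MAG is
# the mean contact-map magnitude. At g_p = 0 the objective reduces exactly
# to the plain sequence-model loss lambda * L_BCE + (1 - lambda) * L_MAG.

BCE_EPS <- 1e-7

#' Loss configuration
#'
#' @param lambda weight between the classification terms and the contact-map
#'   magnitude regularizer (default 0.05)
#' @param g_p relative weight of the GLIDE co-supervision term, in \[0, 1\]
#'   (default 0.2)
#' @param g_t percentile in (0, 100) at which GLIDE scores are binarised
#'   into co-supervision targets (default 92.5)
#' @export
loss_config <- function(lambda = 0.05, g_p = 0.2, g_t = 92.5) {
  assert_that(is.numeric(lambda) && lambda >= 0 && lambda <= 1,
              "lambda must be in [0, 1]")
  assert_that(is.numeric(g_p) && g_p >= 0 && g_p <= 1,
              "g_p must be in [0, 1]")
  assert_that(is.numeric(g_t) && g_t > 0 && g_t < 100,
              "g_t must be a percentile in (0, 100)")
  structure(list(lambda = lambda, g_p = g_p, g_t = g_t),
            class = "loss_config")
}

#' Binary cross-entropy
#'
#' `-[label * log(y) + (1 - label) * log(1 - y)]` with y clamped to
#' (1e-7, 1 - 1e-7).
#' @param y_hat predicted probability in \[0, 1\] (vectorized)
#' @param label observed label in \{0, 1\}
#' @export
loss_bce <- function(y_hat, label) {
  assert_that(all(label %in% c(0, 1)), "labels must be 0/1")
  y <- pmin(pmax(y_hat, BCE_EPS), 1 - BCE_EPS)
  -(label * log(y) + (1 - label) * log(1 - y))
}

#' GLIDE co-supervision loss
#'
#' BCE of the prediction against the binarised GLIDE target. Pairs without
#' a target (endpoint off the scoring network) contribute 0 and are tallied
#' by the training loop.
#' @param y_hat predicted probability
#' @param glide_target 0/1 target (NA = absent)
#' @export
loss_glide <- function(y_hat, glide_target) {
  out <- numeric(length(y_hat))
  ok <- !is.na(glide_target)
  if (any(ok)) out[ok] <- loss_bce(y_hat[ok], glide_target[ok])
  out
}

#' Total multi-objective loss for one pair
#'
#' @param y_hat predicted interaction probability
#' @param label 0/1 interaction label
#' @param glide_target 0/1 binarised GLIDE target (NA = pair excluded from
#'   the co-supervision term)
#' @param contact_mag contact-map magnitude of the prediction
#' @param cfg a [loss_config()]
#' @export
total_loss <- function(y_hat, label, glide_target, contact_mag,
                       cfg = loss_config()) {
  assert_that(inherits(cfg, "loss_config"), "cfg must be a loss_config")
  assert_that(all(is.finite(y_hat)) && all(is.finite(contact_mag)),
              "loss components must be finite")
  cfg$lambda * (loss_bce(y_hat, label) +
                  cfg$g_p * loss_glide(y_hat, glide_target)) +
    (1 - cfg$lambda) * contact_mag
}

# d total_loss / d y_hat for the backward pass (clamped BCE derivative).
loss_dyhat <- function(y_hat, label, glide_target, cfg) {
  y <- pmin(pmax(y_hat, BCE_EPS), 1 - BCE_EPS)
  dbce <- function(target) -target / y + (1 - target) / (1 - y)
  g <- if (!is.na(glide_target)) dbce(glide_target) else 0
  cfg$lambda * (dbce(label) + cfg$g_p * g)
}
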