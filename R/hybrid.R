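# Hybrid score for species with a partial interaction network:
#
#   hybrid(p,q) = GLIDE(p,q) + w * sequence_score(p,q)
#
# The GLIDE weight is fixed to 1 (only the relative weighting matters);
# w is calibrated as the ratio of logistic-regression coefficients
# c_seq / c_glide on held-out labelled pairs. The default w = 0.3268 comes
# from a calibration on a large held-out human PPI corpus and is a sensible
# default when no species-specific calibration data is available.

#' Hybrid combination parameters
#'
#' @param w nonnegative weight of the sequence-model score (default 0.3268)
#' @param provenance free-text provenance ("default-calibration" or a
#'   calibration record from [calibrate_hybrid_weight()])
#' @export
hybrid_params <- function(w = 0.3268, provenance = "default-calibration") {
  assert_that(is.numeric(w) && length(w) == 1L && w >= 0,
              "w must be a nonnegative number")
  structure(list(w = w, provenance = provenance), class = "hybrid_params")
}

#' Hybrid score of network and sequence predictions
#'
#' `glide_score + w * seq_score`, strictly increasing in each argument.
#' Requires both proteins of the pair to be present in the target network
#' (i.e. a defined GLIDE score); for pairs without one, use the sequence
#' score alone.
#'
#' @param glide_score numeric vector of GLIDE scores
#' @param seq_score numeric vector of sequence-model scores
#' @param params a [hybrid_params()]; omitted = default w
#' @export
hybrid_score <- function(glide_score, seq_score, params = hybrid_params()) {
  assert_that(inherits(params, "hybrid_params"), "params must be hybrid_params")
  assert_that(!anyNA(glide_score),
              paste("missing GLIDE score: the hybrid is undefined for pairs",
                    "outside the target network; use the sequence score alone"))
  assert_that(!anyNA(seq_score), "missing sequence score")
  glide_score + params$w * seq_score
}

#' Calibrate the hybrid weight by logistic regression
#'
#' Fits an unregularised maximum-likelihood logistic regression (IRLS,
#' convergence tolerance 1e-8) of the label on the raw GLIDE and sequence
#' scores plus an intercept, and returns w = c_seq / c_glide. Scores are not
#' standardised: w is defined on the raw score scales. The calibration data
#' must be disjoint from the network used to compute the GLIDE inputs and
#' from the sequence model's training pairs; the caller attests this via
#' `disjoint`.
#'
#' @param examples data.frame with columns glide_score, seq_score,
#'   label (0/1)
#' @param disjoint caller's attestation that the calibration pairs are
#'   disjoint from GLIDE's scoring network and the model's training data
#' @return a [hybrid_params()] whose provenance records both coefficients,
#'   n and the class ratio.
#' @export
calibrate_hybrid_weight <- function(examples, disjoint = TRUE) {
  assert_that(all(c("glide_score", "seq_score", "label") %in% names(examples)),
              "examples need glide_score, seq_score and label columns")
  lab <- examples$label
  assert_that(all(lab %in% c(0, 1)), "labels must be 0/1")
  assert_that(sum(lab == 1) >= 2 && sum(lab == 0) >= 2,
              "need at least 2 examples of each class")
  assert_that(stats::sd(examples$glide_score) > 0 &&
                stats::sd(examples$seq_score) > 0,
              "scores must not be constant")
  fit <- glm(lab ~ glide_score + seq_score, data = examples,
             family = binomial(),
             control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  cf <- coef(fit)
  c_glide <- unname(cf["glide_score"])
  c_seq <- unname(cf["seq_score"])
  if (!is.finite(c_glide) || c_glide <= 0) {
    stop(structure(
      class = c("glideppi_calibration_error", "error", "condition"),
      list(message = sprintf(
        paste("calibration failed: the GLIDE coefficient is %0.4g (<= 0),",
              "so w = c_seq / c_glide is undefined; n = %d, positives = %d.",
              "The GLIDE score does not positively separate the classes in",
              "this calibration set."),
        c_glide, nrow(examples), sum(lab == 1)), call = sys.call(-1))))
  }
  record <- list(c_glide = c_glide, c_seq = c_seq,
                 intercept = unname(cf["(Intercept)"]),
                 n = nrow(examples),
                 class_ratio = sum(lab == 0) / sum(lab == 1),
                 converged = fit$converged,
                 disjointness_attested = isTRUE(disjoint))
  hybrid_params(w = c_seq / c_glide, provenance = record)
}
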