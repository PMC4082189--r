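# Evidence aggregation, posterior model probabilities, classification under
# 0-1 and asymmetric utilities, bootstrap accuracy.

#' Subjects x models log-evidence matrix
#'
#' @param log_evidence numeric subjects x models matrix.
#' @param model_ids integer model identifiers (columns).
#' @param subject_ids subject identifiers (rows).
#' @param fill_method optional tag naming the imputation method used.
#' @return an object of class `evidence_matrix`.
#' @export
evidence_matrix <- function(log_evidence, model_ids,
                            subject_ids = seq_len(nrow(log_evidence)),
                            fill_method = NA_character_) {
  log_evidence <- as.matrix(log_evidence)
  assert_that(ncol(log_evidence) == length(model_ids),
              "one model id per column required")
  assert_that(all(is.finite(log_evidence)),
              "evidence matrix must be finite for every subject-model pair")
  dimnames(log_evidence) <- list(subject_ids, model_ids)
  structure(list(log_evidence = log_evidence,
                 model_ids = as.integer(model_ids),
                 subject_ids = subject_ids, fill_method = fill_method),
            class = "evidence_matrix")
}

#' @export
print.evidence_matrix <- function(x, ...) {
  cat(sprintf("<evidence_matrix> %d subjects x %d models (fill: %s)\n",
              nrow(x$log_evidence), ncol(x$log_evidence), x$fill_method))
  invisible(x)
}

#' Posterior model probabilities from log evidences
#'
#' Softmax of log evidence plus log prior, stabilized by subtracting the
#' maximum, so the result is invariant to adding a constant to all log
#' evidences.
#'
#' @param log_ev vector of log evidences.
#' @param model_prior prior model probabilities (default uniform); must be
#'   nonnegative and sum to 1.
#' @return probability vector summing to 1.
#' @export
posterior_model_probs <- function(log_ev, model_prior = NULL) {
  k <- length(log_ev)
  if (is.null(model_prior)) model_prior <- rep(1 / k, k)
  assert_that(length(model_prior) == k, "prior length must match evidence length")
  assert_that(all(model_prior >= 0) && abs(sum(model_prior) - 1) < 1e-8,
              "model prior must be nonnegative and sum to 1")
  lp <- log_ev + log(model_prior)
  if (all(!is.finite(lp))) stop("all log evidences are -Inf")
  w <- exp(lp - max(lp[is.finite(lp)]))
  w / sum(w)
}

#' Fixed-effects group model comparison
#'
#' Sums log evidence across subjects per model (evidence for the group
#' under the assumption that every subject expresses the same model) and
#' converts to posterior model probabilities.
#'
#' @param ev an [evidence_matrix()].
#' @param model_prior prior model probabilities.
#' @return list with `log_group_evidence` (relative, max at 0) and
#'   `posterior` probabilities.
#' @export
ffx_group <- function(ev, model_prior = NULL) {
  stopifnot(inherits(ev, "evidence_matrix"))
  ge <- colSums(ev$log_evidence)
  list(log_group_evidence = ge - max(ge),
       posterior = posterior_model_probs(ge, model_prior),
       model_ids = ev$model_ids)
}

#' Classify one subject by highest model evidence
#'
#' Argmax of the posterior model probability (equivalently of log evidence
#' plus log prior), i.e. the Bayes decision under a 0-1 loss. Exact ties
#' are broken deterministically in favour of the lowest model id.
#'
#' @param log_ev vector of log evidences for one subject.
#' @param model_prior prior model probabilities.
#' @param model_ids model identifiers (defaults to names or index).
#' @return the selected model id.
#' @export
classify <- function(log_ev, model_prior = NULL, model_ids = NULL) {
  if (is.null(model_ids))
    model_ids <- as.integer(names(log_ev) %||% seq_along(log_ev))
  p <- posterior_model_probs(log_ev, model_prior)
  ord <- order(model_ids)
  model_ids[ord][which.max(p[ord])]
}

#' Expected-utility decision from model posteriors
#'
#' Maximizes the expected utility sum_m p(m | data) U(m, d) over decisions
#' d. With a 0-1 utility (identity matrix) this reduces to [classify()].
#' Ties are broken in favour of the lowest decision index.
#'
#' @param log_ev vector of log evidences.
#' @param utility models x decisions utility matrix (finite).
#' @param model_prior prior model probabilities.
#' @return the index (or column name) of the chosen decision.
#' @export
decide_with_utility <- function(log_ev, utility, model_prior = NULL) {
  utility <- as.matrix(utility)
  assert_that(nrow(utility) == length(log_ev),
              "utility must have one row per model")
  assert_that(all(is.finite(utility)), "utility must be finite")
  p <- posterior_model_probs(log_ev, model_prior)
  eu <- as.numeric(crossprod(utility, p))
  d <- which.max(eu)  # which.max takes the first maximum: lowest index wins
  colnames(utility)[d] %||% d
}

#' Classification accuracy with bootstrap resampling
#'
#' Point accuracy over scored instances plus `n_boot` bootstrap resamples
#' (with replacement over instances) of the accuracy, the display behind
#' box-plot accuracy variances.
#'
#' @param truth vector of true model ids.
#' @param predicted vector of predicted model ids (same length).
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @return an object of class `classification_result` with fields
#'   `predicted`, `accuracy`, `bootstrap_samples`, `n_boot`, `seed`.
#' @export
accuracy_with_bootstrap <- function(truth, predicted, n_boot = 1000, seed = NULL) {
  assert_that(length(truth) == length(predicted),
              "truth and predicted must have equal length")
  hit <- as.numeric(truth == predicted)
  n <- length(hit)
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(b)
    mean(hit[sample.int(n, n, replace = TRUE)]), numeric(1)))
  structure(list(predicted = predicted, accuracy = mean(hit),
                 bootstrap_samples = boot, n_boot = n_boot, n = n,
                 seed = seed),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> accuracy %.4f (n = %d; bootstrap sd %.4f over %d resamples)\n",
              x$accuracy, x$n, stats::sd(x$bootstrap_samples), x$n_boot))
  invisible(x)
}

#' Classify every subject of an evidence matrix
#'
#' @param ev an [evidence_matrix()].
#' @param model_prior prior model probabilities.
#' @return integer vector of predicted model ids, one per subject.
#' @export
classify_all <- function(ev, model_prior = NULL) {
  stopifnot(inherits(ev, "evidence_matrix"))
  apply(ev$log_evidence, 1, classify, model_prior = model_prior,
        model_ids = ev$model_ids)
}
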