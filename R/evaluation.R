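#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a uniformly
#' drawn positive outscores a uniformly drawn negative, counting ties as
#' one half. Equivalent to trapezoidal integration of the ROC curve and
#' invariant under any strictly monotone transform of the scores.
#'
#' @param scores Numeric score vector (higher = more likely positive).
#' @param labels Binary 0/1 vector.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  check_metric_input(scores, labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: both classes must be present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise average precision: instances are ranked by descending score
#' (ties broken by ascending original index, making the value
#' deterministic), and precision is averaged over the ranks at which
#' positives occur. No trapezoidal interpolation of the PR curve is
#' applied; this is the average-precision dialect of AUPR. For random
#' scores it converges to the positive prevalence.
#'
#' @inheritParams auc_score
#' @return AUPR in (0, 1].
#' @export
aupr_score <- function(scores, labels) {
  labels <- as.integer(labels)
  check_metric_input(scores, labels)
  if (sum(labels == 1) == 0) stop("AUPR undefined: no positives")
  ord <- order(-scores, seq_along(scores))
  y <- labels[ord]
  precision_at <- cumsum(y) / seq_along(y)
  mean(precision_at[y == 1])
}

check_metric_input <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels lengths differ")
  }
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (anyNA(scores)) stop("scores contain NA")
  invisible(TRUE)
}

#' Cross-validated evaluation of the full DTI pipeline
#'
#' Runs the whole method under stratified k-fold cross-validation over
#' drug-target pairs: pairs are sampled once ([sample_pairs()]), similarity
#' matrices computed via [similarity_pipeline()], pair features built, and
#' per fold a cascade is fit on the remaining folds and scored on the
#' held-out fold with AUC and AUPR.
#'
#' By default the GIP kernels are computed from the full adjacency matrix
#' before splitting, which mirrors the common protocol in this literature
#' but lets held-out interactions influence the features. Set
#' `mask_test_interactions = TRUE` to recompute the kernels per fold with
#' the held-out positives zeroed out of Y (honest but slower and typically
#' lower-scoring).
#'
#' @param interactions An `interaction_matrix`.
#' @param fingerprints A `fingerprint_set`.
#' @param diseases A `disease_profiles` or `NULL`.
#' @param config A [cascade_config()].
#' @param k Number of outer folds (default 10).
#' @param negative_ratio Passed to [sample_pairs()].
#' @param seed Seed for pair sampling and fold assignment.
#' @param mask_test_interactions Recompute kernels with test positives
#'   masked (leakage control).
#' @param ... Further arguments to [similarity_pipeline()] (alphas, gammas,
#'   zero-profile policy).
#' @return A `cv_result`: per-fold AUC/AUPR, their means, fold assignments,
#'   prevalence, seed and config snapshot.
#' @export
cross_validate <- function(interactions, fingerprints, diseases = NULL,
                           config = cascade_config(), k = 10L,
                           negative_ratio = 1, seed = 0L,
                           mask_test_interactions = FALSE, ...) {
  stopifnot(inherits(interactions, "interaction_matrix"))
  if (k < 2) stop("k must be >= 2")
  sampled <- sample_pairs(interactions, negative_ratio,
                          seed = derive_seed(seed, 1))
  pairs <- sampled$pairs
  y <- sampled$labels
  if (min(table(y)) < k) stop("too few pairs of some class for ", k, " folds")
  folds <- stratified_folds(y, k, derive_seed(seed, 2))

  sims <- if (!mask_test_interactions) {
    similarity_pipeline(interactions, fingerprints, diseases, ...)
  }

  fold_auc <- fold_aupr <- numeric(k)
  for (fold in seq_len(k)) {
    test <- folds == fold
    fs <- if (mask_test_interactions) {
      Ym <- interactions$Y
      held <- pairs[test & y == 1, , drop = FALSE]
      Ym[held] <- 0
      masked <- interaction_matrix(interactions$drug_ids,
                                   interactions$target_ids, Ym)
      similarity_pipeline(masked, fingerprints, diseases, ...)
    } else {
      sims
    }
    X <- build_pair_features(fs$sim_drug, fs$sim_tar, pairs)
    cfg <- config
    cfg$seed <- derive_seed(seed, 100 + fold)
    model <- fit_cascade(X[!test, , drop = FALSE], y[!test], cfg)
    s <- predict(model, X[test, , drop = FALSE], type = "score")
    fold_auc[fold] <- auc_score(s, y[test])
    fold_aupr[fold] <- aupr_score(s, y[test])
  }

  structure(list(fold_auc = fold_auc, fold_aupr = fold_aupr,
                 mean_auc = mean(fold_auc), mean_aupr = mean(fold_aupr),
                 folds = folds, pairs = pairs, labels = y,
                 prevalence = mean(y), seed = seed,
                 negative_ratio = negative_ratio,
                 mask_test_interactions = mask_test_interactions,
                 config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(paste0(
    "cv_result: %d-fold CV over %d pairs (prevalence %.3f)\n",
    "  mean AUC  %.4f  (folds: %s)\n",
    "  mean AUPR %.4f  (folds: %s)\n"),
    length(x$fold_auc), length(x$labels), x$prevalence,
    x$mean_auc, paste(sprintf("%.3f", x$fold_auc), collapse = " "),
    x$mean_aupr, paste(sprintf("%.3f", x$fold_aupr), collapse = " ")))
  invisible(x)
}
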