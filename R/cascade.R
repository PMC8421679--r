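#' Configuration for the cascade deep forest
#'
#' The default configuration follows the published setup: each level holds
#' six forests — two completely-random tree forests, two gradient-boosted
#' tree forests and two extremely-randomized tree forests — of 1,000 trees
#' each (6,000 trees per level). Class vectors are generated by 10-fold
#' cross-validation, and levels are added while the out-of-fold level metric
#' improves, up to `max_levels`.
#'
#' `trees_per_forest = 1000` is the published operating point; tests and
#' desk-scale runs use far fewer trees (the cascade is insensitive to this
#' within reason, and the test profile is documented with the package).
#'
#' @param forest_specs Named integer vector mapping forest type to count per
#'   level. Types: `completely_random`, `gradient_boosting`, `extra_trees`.
#' @param trees_per_forest Trees (or boosting rounds) per forest.
#' @param cv_folds Folds for out-of-fold class-vector generation.
#' @param max_levels Safety cap on cascade depth.
#' @param early_stop_tolerance Minimum out-of-fold metric gain required to
#'   keep deepening (default 0: any strict improvement continues).
#' @param level_metric Metric steering depth: `"aupr"` (default), `"auc"`,
#'   or `"accuracy"`.
#' @param seed Root seed; all per-forest streams derive from it.
#' @return A `cascade_config` list.
#' @export
cascade_config <- function(forest_specs = c(completely_random = 2L,
                                            gradient_boosting = 2L,
                                            extra_trees = 2L),
                           trees_per_forest = 1000L,
                           cv_folds = 10L,
                           max_levels = 10L,
                           early_stop_tolerance = 0,
                           level_metric = c("aupr", "auc", "accuracy"),
                           seed = 0L) {
  level_metric <- match.arg(level_metric)
  known <- c("completely_random", "gradient_boosting", "extra_trees")
  if (is.null(names(forest_specs)) || !all(names(forest_specs) %in% known)) {
    stop("forest_specs must be named with types among: ",
         paste(known, collapse = ", "))
  }
  forest_specs <- vapply(forest_specs, as.integer, 0L)
  if (sum(forest_specs) < 1) stop("need at least one forest per level")
  if (trees_per_forest < 1) stop("trees_per_forest must be >= 1")
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  if (max_levels < 1) stop("max_levels must be >= 1")
  if (early_stop_tolerance < 0) stop("early_stop_tolerance must be >= 0")
  structure(list(forest_specs = forest_specs,
                 trees_per_forest = as.integer(trees_per_forest),
                 cv_folds = as.integer(cv_folds),
                 max_levels = as.integer(max_levels),
                 early_stop_tolerance = early_stop_tolerance,
                 level_metric = level_metric,
                 seed = as.integer(seed)),
            class = "cascade_config")
}

level_metric_fun <- function(metric) {
  switch(metric,
         aupr = function(s, y) aupr_score(s, y),
         auc = function(s, y) auc_score(s, y),
         accuracy = function(s, y) mean((s >= 0.5) == (y == 1)))
}

# expand the spec into an ordered vector of forest types
expand_specs <- function(forest_specs) {
  unlist(mapply(rep, names(forest_specs), forest_specs,
                SIMPLIFY = FALSE), use.names = FALSE)
}

#' Fit a cascade deep forest
#'
#' Levels are trained greedily. Level 1 sees the raw features; every deeper
#' level sees the raw features concatenated with the previous level's
#' out-of-fold class vectors (one probability vector per forest, so the
#' augmented width is `raw + n_forests * 2`). Each forest's class vectors
#' are produced by stratified k-fold cross-validation: an instance's vector
#' always comes from a fold model that never saw it, which limits
#' overfitting and gives an honest per-level validation metric. Training
#' stops when a new level fails to improve the out-of-fold metric by more
#' than `early_stop_tolerance` (or at `max_levels`), and the cascade is
#' truncated to the best-scoring level (earliest on ties).
#'
#' @param X Numeric feature matrix.
#' @param y Binary 0/1 labels.
#' @param config A [cascade_config()].
#' @return A `cascade_model` with elements `levels` (fitted forests),
#'   `level_metrics`, `best_level`, `n_raw_features`, `folds`, `config`.
#' @examples
#' \donttest{
#' set.seed(1)
#' X <- rbind(matrix(rnorm(200, 0), 50), matrix(rnorm(200, 2), 50))
#' y <- rep(c(0, 1), each = 50)
#' m <- fit_cascade(X, y, cascade_config(trees_per_forest = 20, cv_folds = 3))
#' head(predict_proba(m, X))
#' }
#' @export
fit_cascade <- function(X, y, config = cascade_config()) {
  stopifnot(inherits(config, "cascade_config"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("X and y lengths differ")
  if (length(unique(y)) < 2) stop("y contains a single class")
  if (nrow(X) < config$cv_folds) {
    stop("fewer samples (", nrow(X), ") than cv_folds (", config$cv_folds,
         ")")
  }
  types <- expand_specs(config$forest_specs)
  n_forests <- length(types)
  metric_fun <- level_metric_fun(config$level_metric)
  folds <- stratified_folds(y, config$cv_folds, derive_seed(config$seed, 0))

  levels <- list()
  level_metrics <- numeric(0)
  best_metric <- -Inf
  best_level <- 0L
  A <- X

  for (lev in seq_len(config$max_levels)) {
    forests <- vector("list", n_forests)
    oof <- matrix(NA_real_, nrow(X), 2 * n_forests)
    for (f in seq_len(n_forests)) {
      fold_models <- vector("list", config$cv_folds)
      for (k in seq_len(config$cv_folds)) {
        tr <- folds != k
        seed_fk <- derive_seed(config$seed,
                               (lev - 1L) * 4096L + (f - 1L) * 64L + k)
        fold_models[[k]] <- build_forest(A[tr, , drop = FALSE], y[tr],
                                         forest_type = types[f],
                                         trees = config$trees_per_forest,
                                         seed = seed_fk)
        oof[!tr, (2 * f - 1):(2 * f)] <-
          predict(fold_models[[k]], A[!tr, , drop = FALSE])
      }
      forests[[f]] <- list(forest_type = types[f], fold_models = fold_models)
    }
    oof_pos <- rowMeans(oof[, seq(2, 2 * n_forests, by = 2), drop = FALSE])
    metric <- metric_fun(oof_pos, y)
    levels[[lev]] <- forests
    level_metrics[lev] <- metric

    # best_level = argmax metric (earliest on ties); deepening continues
    # only while the gain over the previous best exceeds the tolerance
    gain <- metric - best_metric
    if (gain > 0) {
      best_metric <- metric
      best_level <- lev
    }
    if (lev > 1 && gain <= config$early_stop_tolerance) break
    A <- cbind(X, oof)
  }

  levels <- levels[seq_len(best_level)]
  structure(list(levels = levels,
                 level_metrics = level_metrics,
                 best_level = best_level,
                 n_raw_features = ncol(X),
                 n_forests = length(types),
                 forest_types = types,
                 folds = folds,
                 config = config),
            class = "cascade_model")
}

#' @export
print.cascade_model <- function(x, ...) {
  cat(sprintf(paste0(
    "cascade_model: %d level(s) retained (of %d trained), %d forests x %d ",
    "trees per level\n  out-of-fold %s by level: %s\n"),
    x$best_level, length(x$level_metrics), x$n_forests,
    x$config$trees_per_forest, x$config$level_metric,
    paste(sprintf("%.4f", x$level_metrics), collapse = ", ")))
  invisible(x)
}

# class vector of one trained forest on new data: average of its fold models
forest_class_vector <- function(forest, A) {
  P <- 0
  for (fm in forest$fold_models) P <- P + predict(fm, A)
  P / length(forest$fold_models)
}

#' Predict interaction probabilities with a trained cascade
#'
#' Inputs are propagated level by level: at each level every forest emits a
#' class vector (averaged over its cross-validation fold models), the
#' vectors are appended to the raw features, and the next level consumes the
#' augmented matrix. The final score is the mean of the last retained
#' level's forest class vectors.
#'
#' @param model A `cascade_model`.
#' @param X Feature matrix with the raw-feature width seen at fit time.
#' @return Matrix with columns `"0"` and `"1"`; rows are probability
#'   vectors summing to 1.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "cascade_model"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != model$n_raw_features) {
    stop("feature width mismatch: model expects ", model$n_raw_features,
         " raw features, got ", ncol(X))
  }
  A <- X
  for (lev in seq_len(model$best_level)) {
    vectors <- lapply(model$levels[[lev]], forest_class_vector, A = A)
    if (lev < model$best_level) {
      A <- cbind(X, do.call(cbind, vectors))
    } else {
      P <- Reduce(`+`, vectors) / length(vectors)
      colnames(P) <- c("0", "1")
      return(P)
    }
  }
}

#' @export
#' @rdname predict_proba
#' @param object A `cascade_model`.
#' @param newdata Feature matrix.
#' @param type `"prob"` for the probability matrix, `"score"` for the
#'   positive-class probability vector.
#' @param ... Unused.
predict.cascade_model <- function(object, newdata,
                                  type = c("prob", "score"), ...) {
  type <- match.arg(type)
  P <- predict_proba(object, newdata)
  if (type == "score") P[, "1"] else P
}
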