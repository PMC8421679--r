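# single-forest wrappers around the compiled tree learners

#' Fit one tree-ensemble forest
#'
#' The cascade's base learners, three flavours:
#' \describe{
#'   \item{`completely_random`}{each node splits on one uniformly chosen
#'     feature at a uniform random threshold, trees grown until every leaf
#'     is class-pure;}
#'   \item{`extra_trees`}{extremely-randomized trees: `sqrt(p)` candidate
#'     features per node, one random threshold each, best Gini gain wins,
#'     grown to purity;}
#'   \item{`gradient_boosting`}{depth-3 randomized regression trees fit to
#'     logistic-loss gradients with Newton leaf values and shrinkage 0.1;
#'     `trees` is the number of boosting rounds.}
#' }
#' A forest's class vector for an instance is the leaf class-proportion
#' estimate averaged over its trees (for boosting, the boosted probability).
#'
#' @param X Numeric feature matrix.
#' @param y Binary 0/1 label vector.
#' @param forest_type One of `"completely_random"`, `"extra_trees"`,
#'   `"gradient_boosting"`.
#' @param trees Trees per forest (boosting rounds for `gradient_boosting`).
#' @param seed Integer seed; fits are bit-reproducible per seed.
#' @return A `thncdf_forest` object usable with `predict()`.
#' @export
build_forest <- function(X, y,
                         forest_type = c("completely_random", "extra_trees",
                                         "gradient_boosting"),
                         trees = 1000L, seed = 0L) {
  forest_type <- match.arg(forest_type)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  # pure-class data is legal here: trees collapse to a single leaf
  if (trees < 1) stop("need at least one tree")
  n_classes <- 2L

  fit <- switch(forest_type,
    completely_random = .cpp_fit_cls_forest(X, y, n_classes,
                                            as.integer(trees), 0L, 1L,
                                            as.double(seed)),
    extra_trees = .cpp_fit_cls_forest(X, y, n_classes, as.integer(trees),
                                      max(1L, floor(sqrt(ncol(X)))), 1L,
                                      as.double(seed)),
    gradient_boosting = .cpp_fit_gbm(X, y, as.integer(trees), 0.1, 3L,
                                     ncol(X), 2L, 1.0, as.double(seed))
  )
  structure(list(forest_type = forest_type, fit = fit, trees = trees,
                 n_features = ncol(X), n_classes = n_classes, seed = seed),
            class = "thncdf_forest")
}

#' @export
predict.thncdf_forest <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (ncol(X) != object$n_features) {
    stop("feature width mismatch: forest saw ", object$n_features,
         " features, got ", ncol(X))
  }
  P <- if (object$forest_type == "gradient_boosting") {
    p1 <- .cpp_predict_gbm(object$fit, X)
    cbind(1 - p1, p1)
  } else {
    .cpp_predict_cls_forest(object$fit, X, object$n_classes)
  }
  colnames(P) <- c("0", "1")
  P
}

#' @export
print.thncdf_forest <- function(x, ...) {
  cat(sprintf("thncdf_forest: %s, %d trees, %d features\n",
              x$forest_type, x$trees, x$n_features))
  invisible(x)
}
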