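test_that("the default configuration is the published 6 x 1000 setup", {
  cfg <- cascade_config()
  expect_equal(sum(cfg$forest_specs), 6)
  expect_equal(sum(cfg$forest_specs) * cfg$trees_per_forest, 6000)
  expect_equal(cfg$cv_folds, 10L)
  expect_equal(cfg$level_metric, "aupr")
  expect_error(cascade_config(forest_specs = c(bogus = 2L)), "forest_specs")
  expect_error(cascade_config(cv_folds = 1), "cv_folds")
})

test_that("fit_cascade validates its inputs", {
  sd <- separable_data(n = 40, p = 4)
  expect_error(fit_cascade(sd$X, rep(1L, 40), test_cascade_config()),
               "single class")
  expect_error(
    fit_cascade(sd$X[1:4, ], sd$y[c(1, 2, 39, 40)],
                test_cascade_config(cv_folds = 5L)),
    "fewer samples")
})

test_that("max_levels caps the cascade and level 1 separates easy data", {
  sd <- separable_data(n = 200, p = 8)
  m1 <- fit_cascade(sd$X, sd$y,
                    test_cascade_config(trees = 15L, max_levels = 1L,
                                        level_metric = "auc", seed = 2L))
  expect_equal(length(m1$levels), 1)
  expect_equal(m1$best_level, 1L)
  # out-of-fold AUC of level 1 on separable clusters
  expect_gte(m1$level_metrics[1], 0.95)
})

test_that("deeper levels consume raw features plus 6 x 2 class vectors", {
  sd <- separable_data(n = 80, p = 5, shift = 1, seed = 3)
  m <- fit_cascade(sd$X, sd$y,
                   test_cascade_config(trees = 8L, max_levels = 3L, seed = 1L))
  expect_equal(m$n_forests, 6)
  if (m$best_level > 1) {
    widths <- vapply(m$levels[[2]],
                     function(f) f$fold_models[[1]]$n_features, 0L)
    expect_true(all(widths == ncol(sd$X) + m$n_forests * 2))
  }
  # trained metrics exist for every trained level, retained <= trained
  expect_true(m$best_level <= length(m$level_metrics))
  expect_equal(length(m$levels), m$best_level)
})

test_that("early stopping retains the earliest maximal level", {
  sd <- separable_data(n = 80, p = 5, shift = 0.8, seed = 9)
  m <- fit_cascade(sd$X, sd$y,
                   test_cascade_config(trees = 8L, max_levels = 4L, seed = 4L))
  mets <- m$level_metrics
  expect_equal(m$best_level, which.max(mets))
  expect_true(all(mets[m$best_level] >= mets - m$config$early_stop_tolerance))
})

test_that("cascade fits are bit-reproducible per seed", {
  sd <- separable_data(n = 60, p = 4, shift = 1.5, seed = 5)
  cfg <- test_cascade_config(trees = 8L, max_levels = 2L, seed = 11L)
  a <- fit_cascade(sd$X, sd$y, cfg)
  b <- fit_cascade(sd$X, sd$y, cfg)
  newX <- separable_data(n = 30, p = 4, shift = 1.5, seed = 6)$X
  expect_identical(a$level_metrics, b$level_metrics)
  expect_identical(predict_proba(a, newX), predict_proba(b, newX))
})

test_that("predictions are probability rows and a row-wise map", {
  sd <- separable_data(n = 60, p = 4, seed = 7)
  m <- fit_cascade(sd$X, sd$y,
                   test_cascade_config(trees = 8L, max_levels = 2L, seed = 1L))
  P <- predict_proba(m, sd$X)
  expect_true(all(P >= 0))
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-9)

  perm <- sample(nrow(sd$X))
  expect_identical(predict_proba(m, sd$X[perm, ]), P[perm, ])
  expect_error(predict_proba(m, sd$X[, 1:2]), "width mismatch")
})

test_that("out-of-fold class vectors never come from a fold containing the row", {
  # refit the level-1 forests per fold by hand and confirm the stored model
  # reproduces each row's vector from the model not trained on it
  sd <- separable_data(n = 44, p = 4, seed = 8)
  cfg <- test_cascade_config(trees = 6L, cv_folds = 3L, max_levels = 1L,
                             seed = 21L)
  m <- fit_cascade(sd$X, sd$y, cfg)
  folds <- m$folds
  expect_setequal(unique(folds), 1:3)
  # stratified: class balance per fold differs by at most one
  tab <- table(folds, sd$y)
  expect_true(all(apply(tab, 2, function(x) diff(range(x))) <= 1))
  f1 <- m$levels[[1]][[1]]
  for (k in 1:3) {
    tr <- folds != k
    refit <- build_forest(sd$X[tr, , drop = FALSE], sd$y[tr],
                          f1$forest_type, trees = cfg$trees_per_forest,
                          seed = f1$fold_models[[k]]$seed)
    expect_identical(refit$fit, f1$fold_models[[k]]$fit)
  }
})

test_that("cascade AUPR is no worse than a plain 100-tree forest baseline", {
  d <- generate_synthetic(synth_config(m = 20, n = 24, k = 9, seed = 13))
  sims <- similarity_pipeline(d$interactions, d$fingerprints, d$diseases)
  sp <- sample_pairs(d$interactions, 1, seed = 13)
  X <- build_pair_features(sims$sim_drug, sims$sim_tar, sp$pairs)
  n <- nrow(X)
  set.seed(13)
  test <- sample(n, round(n / 3))
  casc <- fit_cascade(X[-test, ], sp$labels[-test],
                      test_cascade_config(trees = 20L, max_levels = 2L,
                                          seed = 1L))
  base <- build_forest(X[-test, ], sp$labels[-test], "extra_trees",
                       trees = 100L, seed = 1L)
  aupr_casc <- aupr_score(predict(casc, X[test, ], type = "score"),
                          sp$labels[test])
  aupr_base <- aupr_score(predict(base, X[test, ])[, "1"], sp$labels[test])
  expect_gte(aupr_casc, aupr_base - 0.02)
})
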