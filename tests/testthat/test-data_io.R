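test_that("read_interactions parses the benchmark dialect and orients by prefix", {
  path <- toy_interaction_file()
  im <- read_interactions(path)
  expect_s3_class(im, "interaction_matrix")
  expect_equal(length(im$drug_ids), 2)
  expect_equal(length(im$target_ids), 3)
  expect_equal(sum(im$Y), 4)
  expect_equal(im$Y["D1", "hsa2"], 1)
  expect_equal(im$Y["D1", "hsa3"], 0)

  # explicit orientation overrides the heuristic
  im2 <- read_interactions(path, orientation = "drugs_as_columns")
  expect_identical(im$Y, im2$Y)
})

test_that("read_interactions is orientation-invariant under transposition", {
  set.seed(7)
  Y <- matrix(rbinom(20, 1, 0.4), 4, 5,
              dimnames = list(paste0("D", 1:4), paste0("hsa", 1:5)))
  f_cols <- write_matrix_tsv(t(Y), colnames(Y), rownames(Y)) # targets on rows
  f_rows <- write_matrix_tsv(Y, rownames(Y), colnames(Y))    # drugs on rows
  a <- read_interactions(f_cols, orientation = "drugs_as_columns")
  b <- read_interactions(f_rows, orientation = "drugs_as_rows")
  expect_identical(a$Y, b$Y)
  expect_identical(a$drug_ids, b$drug_ids)
})

test_that("read_interactions rejects bad input with located errors", {
  bad <- write_matrix_tsv(rbind(c(1, 0), c(2, 1)), c("hsa1", "hsa2"),
                          c("D1", "D2"))
  expect_error(read_interactions(bad), "non-binary cell.*hsa2.*D1")

  dup <- write_matrix_tsv(rbind(c(1, 0), c(0, 1)), c("hsa1", "hsa1"),
                          c("D1", "D2"))
  expect_error(read_interactions(dup), "duplicate")

  ragged <- tempfile()
  writeLines(c("\tD1\tD2", "hsa1\t1\t0", "hsa2\t1"), ragged)
  expect_error(read_interactions(ragged), "ragged row at line 3")

  # ambiguous identifiers fall back to drugs-as-columns with a warning
  amb <- write_matrix_tsv(rbind(c(1, 0), c(0, 1)), c("x1", "x2"),
                          c("y1", "y2"))
  expect_warning(im <- read_interactions(amb), "assuming drugs")
  expect_identical(im$drug_ids, c("y1", "y2"))
})

test_that("read_fingerprints validates bitstrings", {
  f <- tempfile()
  fp166 <- paste(c("1", "1", rep("0", 164)), collapse = "")
  writeLines(c(paste0("D1\t", fp166), paste0("D2\t", fp166)), f)
  fps <- read_fingerprints(f, 166)
  expect_equal(sum(fps$bits[1, ]), 2) # popcount 2
  # identical bitstrings stay distinct entries
  expect_equal(nrow(fps$bits), 2)
  expect_identical(fps$drug_ids, c("D1", "D2"))

  short <- tempfile()
  writeLines(paste0("D9\t", substr(fp166, 1, 165)), short)
  expect_error(read_fingerprints(short, 166), "D9")

  nonbit <- tempfile()
  writeLines(paste0("D8\t", sub("1", "2", fp166)), nonbit)
  expect_error(read_fingerprints(nonbit, 166), "D8")
})

test_that("read_target_disease builds a collapsed dense matrix", {
  f <- tempfile()
  writeLines(c("t1\ts1", "t1\ts2", "t2\ts1"), f)
  dp <- read_target_disease(f)
  expect_equal(dim(dp$P), c(2, 2))
  expect_equal(sum(dp$P), 3)

  # duplicate edges are idempotent
  f2 <- tempfile()
  writeLines(c("t1\ts1", "t1\ts2", "t2\ts1", "t1\ts1"), f2)
  expect_identical(read_target_disease(f2)$P, dp$P)

  # k tracks distinct diseases
  f3 <- tempfile()
  writeLines(c("t1\ts1", "t1\ts2", "t2\ts3"), f3)
  expect_equal(length(read_target_disease(f3)$disease_ids), 3)

  empty <- tempfile()
  file.create(empty)
  expect_error(read_target_disease(empty), "no diseases")
})

test_that("similarity matrices round-trip through TSV", {
  S <- matrix(c(1, 1 / 3, 1 / 3, 1), 2, 2)
  sim <- similarity_matrix(c("a", "b"), S)
  path <- tempfile()
  write_similarity(sim, path)
  back <- read_similarity(path)
  expect_identical(back$ids, sim$ids)
  expect_lt(max(abs(back$S - sim$S)), 1e-12)

  # larger random round trip
  set.seed(1)
  n <- 7
  R <- crossprod(matrix(runif(n * n), n)) # symmetric
  R <- R / max(R)
  diag(R) <- 1
  sim2 <- similarity_matrix(letters[1:n], R)
  write_similarity(sim2, path)
  expect_lt(max(abs(read_similarity(path)$S - sim2$S)), 1e-12)

  nonsq <- write_matrix_tsv(matrix(0, 3, 2), c("a", "b", "c"), c("a", "b"))
  expect_error(read_similarity(nonsq), "not square")
})

test_that("model containers persist and refuse foreign files", {
  sd <- separable_data(n = 40, p = 4)
  model <- fit_cascade(sd$X, sd$y,
                       test_cascade_config(trees = 5L, max_levels = 1L))
  path <- tempfile()
  save_model(model, path)
  back <- load_model(path)
  expect_identical(predict_proba(back, sd$X), predict_proba(model, sd$X))

  other <- tempfile()
  saveRDS(list(format = "something-else"), other)
  expect_error(load_model(other), "not a model container")
})
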