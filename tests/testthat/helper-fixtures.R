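# shared fixtures: tiny in-code data sets and independent oracles

# write a labeled TSV matrix in the benchmark dialect (row ids in first
# column, column ids in the header)
write_matrix_tsv <- function(M, row_ids, col_ids, path = tempfile()) {
  con <- file(path, "w")
  writeLines(paste(c("", col_ids), collapse = "\t"), con)
  writeLines(paste(row_ids, apply(M, 1, paste, collapse = "\t"), sep = "\t"),
             con)
  close(con)
  path
}

# 2 drugs x 3 targets with four interactions, written targets-on-rows
toy_interaction_file <- function() {
  Yt <- rbind(c(1, 0), c(1, 1), c(0, 1)) # 3 targets x 2 drugs
  write_matrix_tsv(Yt, c("hsa1", "hsa2", "hsa3"), c("D1", "D2"))
}

random_fingerprints <- function(n, L = 166L, density = 0.25) {
  bits <- matrix(as.double(runif(n * L) < density), n, L)
  fingerprint_set(sprintf("D%02d", seq_len(n)), bits)
}

# --- independent oracles (scalar, brute-force) -----------------------------

oracle_tanimoto <- function(a, b) {
  inter <- 0L
  uni <- 0L
  for (i in seq_along(a)) { # exhaustive bit enumeration
    inter <- inter + (a[i] == 1 && b[i] == 1)
    uni <- uni + (a[i] == 1 || b[i] == 1)
  }
  if (uni == 0) 0 else inter / uni
}

oracle_gip <- function(P, gamma_prime = 1) {
  n <- nrow(P)
  s <- 0
  for (i in seq_len(n)) s <- s + sum(P[i, ]^2)
  gamma <- gamma_prime / (s / n)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- 0
      for (c in seq_len(ncol(P))) d <- d + (P[i, c] - P[j, c])^2
      K[i, j] <- exp(-gamma * d)
    }
  }
  K
}

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

oracle_aupr <- function(scores, labels) {
  ord <- order(-scores, seq_along(scores))
  y <- labels[ord]
  tp <- 0
  prec <- numeric(0)
  for (i in seq_along(y)) {
    if (y[i] == 1) {
      tp <- tp + 1
      prec <- c(prec, tp / i)
    }
  }
  mean(prec)
}

# small separable two-cluster classification problem
separable_data <- function(n = 200, p = 8, shift = 3, seed = 42) {
  set.seed(seed)
  half <- n / 2
  X <- rbind(matrix(rnorm(half * p), half),
             matrix(rnorm(half * p, mean = shift), half))
  # squash into [0, 1] like real similarity features
  X <- (X - min(X)) / (max(X) - min(X))
  list(X = X, y = rep(c(0L, 1L), each = half))
}

# desk-scale cascade configuration used throughout the tests; the published
# operating point (1000 trees, 10 folds) is the package default
test_cascade_config <- function(trees = 25L, cv_folds = 3L, ...) {
  cascade_config(trees_per_forest = trees, cv_folds = cv_folds, ...)
}
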