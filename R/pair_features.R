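#' Encode drug-target pairs as similarity-profile feature vectors
#'
#' A pair `(i, j)` is encoded as the concatenation of drug `i`'s full row of
#' the fused drug similarity matrix (m values) and target `j`'s full row of
#' the fused target similarity matrix (n values), giving an `m + n` feature
#' vector in \[0, 1\]. This is the standard similarity-profile encoding for
#' DTI classifiers: the fused similarity matrices are the sole input.
#'
#' @param sim_drug Fused drug `similarity_matrix` (m drugs).
#' @param sim_tar Fused target `similarity_matrix` (n targets).
#' @param pairs Two-column integer matrix (drug index, target index),
#'   1-based.
#' @return Numeric matrix, one row per pair, `m + n` columns named
#'   `drug_sim_<id>` / `target_sim_<id>`.
#' @export
build_pair_features <- function(sim_drug, sim_tar, pairs) {
  stopifnot(inherits(sim_drug, "similarity_matrix"),
            inherits(sim_tar, "similarity_matrix"))
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("pairs must have two columns (drug, target)")
  m <- nrow(sim_drug$S)
  n <- nrow(sim_tar$S)
  if (any(pairs[, 1] < 1 | pairs[, 1] > m)) {
    stop("drug index out of range [1, ", m, "]")
  }
  if (any(pairs[, 2] < 1 | pairs[, 2] > n)) {
    stop("target index out of range [1, ", n, "]")
  }
  X <- cbind(sim_drug$S[pairs[, 1], , drop = FALSE],
             sim_tar$S[pairs[, 2], , drop = FALSE])
  colnames(X) <- c(paste0("drug_sim_", sim_drug$ids),
                   paste0("target_sim_", sim_tar$ids))
  rownames(X) <- NULL
  X
}

#' Sample labeled drug-target pairs with controlled negative sampling
#'
#' All interacting (positive) pairs are always included. Non-interacting
#' cells are treated as negatives and sampled uniformly without replacement:
#' `round(negative_ratio * n_positives)` of them (capped at the number
#' available), or every zero cell when `negative_ratio = "all"`. Known DTI
#' benchmarks are heavily imbalanced (far more non-interacting cells than
#' interactions), so the ratio is an explicit, reported choice; the default
#' 1:1 is the common link-prediction protocol.
#'
#' @param interactions An `interaction_matrix`.
#' @param negative_ratio Positive number, or `"all"`.
#' @param seed Integer seed making the draw reproducible.
#' @return List with `pairs` (two-column index matrix) and `labels`
#'   (0/1 vector), positives first, negatives in sampled order.
#' @export
sample_pairs <- function(interactions, negative_ratio = 1, seed = 0L) {
  stopifnot(inherits(interactions, "interaction_matrix"))
  Y <- interactions$Y
  pos <- which(Y == 1, arr.ind = TRUE)
  neg <- which(Y == 0, arr.ind = TRUE)
  if (nrow(pos) == 0) stop("Y contains no interactions; nothing to learn")
  if (nrow(neg) == 0) stop("Y is all ones; no negatives to sample")
  # fix a deterministic cell order before sampling so results do not depend
  # on which() internals
  neg <- neg[order(neg[, 1], neg[, 2]), , drop = FALSE]
  pos <- pos[order(pos[, 1], pos[, 2]), , drop = FALSE]

  if (identical(negative_ratio, "all")) {
    take <- seq_len(nrow(neg))
  } else {
    negative_ratio <- as.numeric(negative_ratio)
    if (!is.finite(negative_ratio) || negative_ratio <= 0) {
      stop("negative_ratio must be positive or \"all\"")
    }
    n_neg <- min(nrow(neg), round(negative_ratio * nrow(pos)))
    take <- with_seed(seed, sample.int(nrow(neg), n_neg))
  }
  pairs <- rbind(pos, neg[take, , drop = FALSE])
  dimnames(pairs) <- list(NULL, c("drug", "target"))
  list(pairs = pairs,
       labels = c(rep(1L, nrow(pos)), rep(0L, length(take))))
}
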