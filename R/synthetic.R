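#' Configuration for the synthetic tripartite-network generator
#'
#' The generator plants block structure: drugs and targets are assigned to
#' clusters, interactions are dense within co-clustered (drug, target)
#' blocks and sparse elsewhere, each drug cluster has a prototype
#' fingerprint whose members are noisy copies, and each target cluster is
#' associated with its own disease subset. This emulates the real situation
#' the method exploits — chemically similar drugs hitting related targets
#' that share disease associations — at desk scale.
#'
#' Defaults (m = 40 drugs, n = 50 targets, k = 20 diseases, 3 clusters,
#' p_in = 0.4, p_out = 0.03, 166-bit fingerprints with 10% bit-flip noise)
#' give roughly 300 positive pairs at an overall interaction density of
#' about 15% — denser than the public DTI benchmarks (1-3%) because a
#' desk-scale network needs enough positives for stratified 10-fold CV.
#'
#' @param m,n,k Numbers of drugs, targets and diseases.
#' @param n_clusters Number of planted clusters.
#' @param p_in,p_out Interaction probability within / across clusters
#'   (`0 <= p_out < p_in <= 1`).
#' @param fingerprint_length Bits per fingerprint (166 matches
#'   structural-key fingerprints).
#' @param epsilon Per-bit flip probability away from the cluster prototype
#'   (`0 <= epsilon < 0.5`).
#' @param p_disease Probability of a target-disease edge within the
#'   cluster's disease subset.
#' @param seed Integer seed; generation is bit-reproducible per seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(m = 40L, n = 50L, k = 20L, n_clusters = 3L,
                         p_in = 0.4, p_out = 0.03,
                         fingerprint_length = 166L, epsilon = 0.1,
                         p_disease = 0.5, seed = 0L) {
  if (any(c(m, n, k) < n_clusters)) {
    stop("m, n and k must each be >= n_clusters")
  }
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop("need 0 <= p_out < p_in <= 1")
  }
  if (!(epsilon >= 0 && epsilon < 0.5)) stop("need 0 <= epsilon < 0.5")
  if (fingerprint_length < 1) stop("fingerprint_length must be >= 1")
  structure(list(m = as.integer(m), n = as.integer(n), k = as.integer(k),
                 n_clusters = as.integer(n_clusters), p_in = p_in,
                 p_out = p_out,
                 fingerprint_length = as.integer(fingerprint_length),
                 epsilon = epsilon, p_disease = p_disease,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic tripartite drug-target-disease network
#'
#' See [synth_config()] for the planted-block model. If the drawn adjacency
#' matrix is degenerate (all zeros or all ones) it is resampled once from a
#' derived seed, with a message.
#'
#' @param config A [synth_config()].
#' @return List with `interactions` (`interaction_matrix`), `fingerprints`
#'   (`fingerprint_set`), `diseases` (`disease_profiles`), and the planted
#'   `drug_clusters` / `target_clusters` assignments.
#' @export
generate_synthetic <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  out <- with_seed(config$seed, generate_once(config))
  if (all(out$interactions$Y == 0) || all(out$interactions$Y == 1)) {
    message("degenerate adjacency drawn; resampling once")
    out <- with_seed(derive_seed(config$seed, 99), generate_once(config))
    if (all(out$interactions$Y == 0) || all(out$interactions$Y == 1)) {
      stop("degenerate adjacency after resampling; adjust p_in/p_out")
    }
  }
  out
}

generate_once <- function(cfg) {
  drug_ids <- sprintf("D%03d", seq_len(cfg$m))
  target_ids <- sprintf("hsa%03d", seq_len(cfg$n))
  disease_ids <- sprintf("DIS%03d", seq_len(cfg$k))

  dc <- rep_len(seq_len(cfg$n_clusters), cfg$m)
  tc <- rep_len(seq_len(cfg$n_clusters), cfg$n)
  sc <- rep_len(seq_len(cfg$n_clusters), cfg$k) # disease subsets

  same <- outer(dc, tc, `==`)
  p <- ifelse(same, cfg$p_in, cfg$p_out)
  Y <- matrix(as.double(runif(cfg$m * cfg$n) < p), cfg$m, cfg$n)

  prototypes <- matrix(as.double(runif(cfg$n_clusters *
                                         cfg$fingerprint_length) < 0.25),
                       cfg$n_clusters, cfg$fingerprint_length)
  flips <- matrix(runif(cfg$m * cfg$fingerprint_length) < cfg$epsilon,
                  cfg$m, cfg$fingerprint_length)
  bits <- abs(prototypes[dc, , drop = FALSE] - flips)

  within <- outer(tc, sc, `==`)
  P <- matrix(as.double(within & (runif(cfg$n * cfg$k) < cfg$p_disease)),
              cfg$n, cfg$k)

  list(interactions = interaction_matrix(drug_ids, target_ids, Y),
       fingerprints = fingerprint_set(drug_ids, bits),
       diseases = disease_profiles(target_ids, disease_ids, P),
       drug_clusters = dc, target_clusters = tc)
}

#' Write a synthetic data set to disk in the package's file dialects
#'
#' Produces the three input files consumed by the readers:
#' `interactions.tsv` (targets on rows, drugs on columns — the benchmark
#' layout), `fingerprints.tsv` and `target_disease.tsv`.
#'
#' @param data Output of [generate_synthetic()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_synthetic <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(interactions = file.path(dir, "interactions.tsv"),
             fingerprints = file.path(dir, "fingerprints.tsv"),
             target_disease = file.path(dir, "target_disease.tsv"))

  im <- data$interactions
  tY <- t(im$Y) # benchmark layout: targets on rows, drugs on columns
  con <- file(paths[["interactions"]], "w")
  writeLines(paste(c("", im$drug_ids), collapse = "\t"), con)
  writeLines(paste(im$target_ids,
                   apply(tY, 1, paste, collapse = "\t"), sep = "\t"), con)
  close(con)

  fp <- data$fingerprints
  writeLines(paste(fp$drug_ids,
                   apply(fp$bits, 1, paste, collapse = ""), sep = "\t"),
             paths[["fingerprints"]])

  dp <- data$diseases
  edges <- which(dp$P == 1, arr.ind = TRUE)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  writeLines(paste(dp$target_ids[edges[, 1]], dp$disease_ids[edges[, 2]],
                   sep = "\t"),
             paths[["target_disease"]])

  invisible(paths)
}
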