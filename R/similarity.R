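#' Construct a similarity matrix container
#'
#' A square symmetric matrix with entries in \[0, 1\] and an identifier list.
#' Symmetry is enforced to 1e-12 and tiny negative values arising from
#' floating-point cancellation are clamped to 0.
#'
#' @param ids Unique identifier character vector.
#' @param S Square numeric matrix aligned with `ids`.
#' @return A `similarity_matrix` object.
#' @export
similarity_matrix <- function(ids, S) {
  ids <- as.character(ids)
  S <- as.matrix(S)
  storage.mode(S) <- "double"
  if (anyDuplicated(ids)) stop("duplicate identifiers in similarity matrix")
  if (nrow(S) != ncol(S) || nrow(S) != length(ids)) {
    stop("similarity matrix must be square and aligned with ids")
  }
  if (max(abs(S - t(S))) > 1e-12) stop("similarity matrix is not symmetric")
  S[S < 0 & S > -1e-12] <- 0
  if (any(S < 0 | S > 1)) stop("similarity entries must lie in [0, 1]")
  S <- (S + t(S)) / 2
  dimnames(S) <- list(ids, ids)
  structure(list(ids = ids, S = S), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  off <- x$S[upper.tri(x$S)]
  cat(sprintf(
    "similarity_matrix: %d x %d, off-diagonal mean %.4f (range %.4f-%.4f)\n",
    nrow(x$S), ncol(x$S), mean(off), min(off), max(off)))
  invisible(x)
}

#' Tanimoto chemical similarity between binary fingerprints
#'
#' The Tanimoto (Jaccard) coefficient between two fingerprints is the number
#' of bits set in both divided by the number set in either:
#' `|a AND b| / (|a| + |b| - |a AND b|)`. Pairs where both fingerprints are
#' all-zero have an undefined 0/0 coefficient; absence of any substructure
#' evidence is not treated as similarity, so those pairs score 0
#' off-diagonal (the diagonal is always 1).
#'
#' @param fps A `fingerprint_set`.
#' @return A `similarity_matrix` over the drugs.
#' @examples
#' fps <- fingerprint_set(c("a", "b"),
#'                        rbind(c(1, 1, 0, 0), c(1, 0, 1, 0)))
#' tanimoto_matrix(fps)$S["a", "b"] # 1/3
#' @export
tanimoto_matrix <- function(fps) {
  stopifnot(inherits(fps, "fingerprint_set"))
  B <- fps$bits
  inter <- B %*% t(B)               # |a AND b|
  pc <- rowSums(B)                  # popcounts
  uni <- outer(pc, pc, `+`) - inter # |a OR b|
  S <- ifelse(uni > 0, inter / uni, 0)
  diag(S) <- 1
  similarity_matrix(fps$drug_ids, S)
}

#' Gaussian interaction-profile kernel bandwidth
#'
#' The kernel width is normalized by the mean squared norm of the profiles:
#' `gamma = gamma_prime / mean_i ||p_i||^2`. For binary profiles the squared
#' norm is the row sum, so denser interaction profiles yield a narrower
#' kernel.
#'
#' @param profiles Binary matrix, one profile per row.
#' @param gamma_prime Positive scale factor (default 1).
#' @return The bandwidth `gamma`, a positive scalar.
#' @examples
#' gip_bandwidth(rbind(c(1, 0), c(1, 1))) # 1 / 1.5
#' @export
gip_bandwidth <- function(profiles, gamma_prime = 1) {
  profiles <- as.matrix(profiles)
  if (gamma_prime <= 0) stop("gamma_prime must be positive")
  msq <- mean(rowSums(profiles^2))
  if (msq == 0) stop("degenerate profiles: bandwidth undefined")
  gamma_prime / msq
}

#' Gaussian interaction-profile (GIP) kernel
#'
#' Kernel entry `(i, j)` is `exp(-gamma * ||p_i - p_j||^2)` with the
#' bandwidth from [gip_bandwidth()]. Applied literally, two entities that
#' both have all-zero profiles come out perfectly similar (distance 0);
#' `zero_profile_policy = "formula"` keeps that literal behaviour while
#' `"zero"` sets such off-diagonal pairs to 0.
#'
#' @param profiles Binary matrix, one profile per row; row names (if any)
#'   become the similarity identifiers.
#' @param gamma_prime Positive bandwidth scale (default 1).
#' @param zero_profile_policy `"formula"` (literal kernel) or `"zero"`.
#' @param ids Optional identifiers overriding row names.
#' @return A `similarity_matrix`.
#' @examples
#' gip_kernel(rbind(c(1, 0), c(0, 1)))$S[1, 2] # exp(-2)
#' @export
gip_kernel <- function(profiles, gamma_prime = 1,
                       zero_profile_policy = c("formula", "zero"),
                       ids = NULL) {
  zero_profile_policy <- match.arg(zero_profile_policy)
  profiles <- as.matrix(profiles)
  storage.mode(profiles) <- "double"
  if (is.null(ids)) {
    ids <- rownames(profiles) %||% paste0("p", seq_len(nrow(profiles)))
  }
  gamma <- gip_bandwidth(profiles, gamma_prime)
  D <- .cpp_sq_dist(profiles)
  D[D < 0] <- 0 # cancellation guard
  S <- exp(-gamma * D)
  diag(S) <- 1
  if (zero_profile_policy == "zero") {
    z <- rowSums(profiles != 0) == 0
    if (any(z)) {
      S[z, z] <- 0
      diag(S) <- 1
    }
  }
  similarity_matrix(ids, S)
}

#' Fuse two similarity matrices by convex combination
#'
#' `fuse_drug` combines the drug GIP kernel with chemical-structure
#' similarity, `fuse_target` the target GIP kernel with the target-disease
#' GIP kernel: `S = (1 - alpha) * S_gip + alpha * S_other`. The default
#' `alpha = 0.5` weighs both sources equally (the 0.5:0.5 ratio).
#'
#' @param k_gip Drug (or target) GIP `similarity_matrix`.
#' @param sim_chem Chemical-structure `similarity_matrix` (drugs).
#' @param alpha Mixing weight in \[0, 1\] on the second matrix.
#' @return A fused `similarity_matrix`.
#' @export
fuse_drug <- function(k_gip, sim_chem, alpha = 0.5) {
  fuse_pair(k_gip, sim_chem, alpha)
}

#' @rdname fuse_drug
#' @param k_gip_ts Target-disease GIP `similarity_matrix`, aligned to the
#'   same target ordering as `k_gip` (targets without disease data carry
#'   all-zero disease profiles upstream).
#' @export
fuse_target <- function(k_gip, k_gip_ts, alpha = 0.5) {
  fuse_pair(k_gip, k_gip_ts, alpha)
}

fuse_pair <- function(a, b, alpha) {
  stopifnot(inherits(a, "similarity_matrix"), inherits(b, "similarity_matrix"))
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (!identical(a$ids, b$ids)) {
    d <- c(setdiff(a$ids, b$ids), setdiff(b$ids, a$ids))
    stop("identifier mismatch between similarity matrices",
         if (length(d)) paste0("; symmetric difference: ",
                               paste(d, collapse = ", "))
         else "; same identifiers in different order")
  }
  similarity_matrix(a$ids, (1 - alpha) * a$S + alpha * b$S)
}

#' Compute all fused similarity matrices for a tripartite network
#'
#' Convenience wrapper running the full similarity stage: Tanimoto chemical
#' similarity, drug/target GIP kernels from the adjacency matrix, the
#' target-disease GIP kernel from disease profiles (targets absent from the
#' disease data get all-zero profiles), and the two fusions.
#'
#' @param interactions An `interaction_matrix`.
#' @param fingerprints A `fingerprint_set` covering at least the drugs in
#'   `interactions` (set `allow_missing_fingerprints = TRUE` to substitute
#'   all-zero fingerprints with a warning).
#' @param diseases A `disease_profiles` object, or `NULL` for no disease
#'   layer (all-zero profiles).
#' @param alpha_drug,alpha_target Fusion weights (default 0.5 each).
#' @param gamma_prime_drug,gamma_prime_target,gamma_prime_disease GIP
#'   bandwidth scales (default 1 each).
#' @param zero_profile_policy Passed to [gip_kernel()].
#' @param allow_missing_fingerprints Substitute all-zero fingerprints for
#'   drugs missing from `fingerprints` instead of erroring.
#' @return List with `sim_drug` and `sim_tar` (`similarity_matrix` objects),
#'   plus the intermediate `sim_chem`, `k_gip_d`, `k_gip_t`, `k_gip_ts`.
#' @export
similarity_pipeline <- function(interactions, fingerprints, diseases = NULL,
                                alpha_drug = 0.5, alpha_target = 0.5,
                                gamma_prime_drug = 1, gamma_prime_target = 1,
                                gamma_prime_disease = 1,
                                zero_profile_policy = c("formula", "zero"),
                                allow_missing_fingerprints = FALSE) {
  zero_profile_policy <- match.arg(zero_profile_policy)
  stopifnot(inherits(interactions, "interaction_matrix"),
            inherits(fingerprints, "fingerprint_set"))
  Y <- interactions$Y
  drugs <- interactions$drug_ids
  targets <- interactions$target_ids

  missing <- setdiff(drugs, fingerprints$drug_ids)
  if (length(missing)) {
    if (!allow_missing_fingerprints) {
      stop("no fingerprint for drug(s): ", paste(missing, collapse = ", "),
           " (set allow_missing_fingerprints = TRUE to substitute zeros)")
    }
    warning("substituting all-zero fingerprints for ", length(missing),
            " drug(s) without fingerprint data")
  }
  B <- matrix(0, nrow = length(drugs), ncol = ncol(fingerprints$bits),
              dimnames = list(drugs, NULL))
  present <- intersect(drugs, fingerprints$drug_ids)
  B[present, ] <- fingerprints$bits[present, , drop = FALSE]
  sim_chem <- tanimoto_matrix(fingerprint_set(drugs, B))

  k_gip_d <- gip_kernel(Y, gamma_prime_drug, zero_profile_policy, ids = drugs)
  k_gip_t <- gip_kernel(t(Y), gamma_prime_target, zero_profile_policy,
                        ids = targets)

  if (is.null(diseases)) {
    P <- matrix(0, nrow = length(targets), ncol = 1,
                dimnames = list(targets, "none"))
  } else {
    stopifnot(inherits(diseases, "disease_profiles"))
    P <- matrix(0, nrow = length(targets), ncol = length(diseases$disease_ids),
                dimnames = list(targets, diseases$disease_ids))
    shared <- intersect(targets, diseases$target_ids)
    P[shared, ] <- diseases$P[shared, , drop = FALSE]
  }
  # the bandwidth is normalized over the padded, target-aligned matrix
  k_gip_ts <- if (all(P == 0)) {
    # no disease signal at all: policy decides between all-ones and identity
    S <- if (zero_profile_policy == "formula") {
      matrix(1, length(targets), length(targets))
    } else {
      diag(length(targets))
    }
    similarity_matrix(targets, S)
  } else {
    gip_kernel(P, gamma_prime_disease, zero_profile_policy, ids = targets)
  }

  list(sim_drug = fuse_drug(k_gip_d, sim_chem, alpha_drug),
       sim_tar = fuse_target(k_gip_t, k_gip_ts, alpha_target),
       sim_chem = sim_chem, k_gip_d = k_gip_d, k_gip_t = k_gip_t,
       k_gip_ts = k_gip_ts)
}

#' Structural-key fingerprints from SMILES strings (optional helper)
#'
#' Computes 166-bit structural-key (MACCS) fingerprints by delegating to a
#' Python cheminformatics toolkit (RDKit) found on `PATH`. This is an
#' optional convenience: the core pipeline consumes fingerprint TSVs and
#' never requires a toolkit.
#'
#' @param smiles Named character vector: names are drug identifiers, values
#'   SMILES strings.
#' @param python Python interpreter to use (default `"python"`).
#' @return A `fingerprint_set` with 166-bit vectors.
#' @export
fingerprints_from_smiles <- function(smiles, python = "python") {
  if (!length(smiles)) stop("no SMILES given")
  if (is.null(names(smiles)) || any(!nzchar(names(smiles)))) {
    stop("smiles must be a named vector (names are drug identifiers)")
  }
  if (any(!nzchar(smiles))) {
    stop("empty SMILES for drug '", names(smiles)[!nzchar(smiles)][1], "'")
  }
  if (Sys.which(python) == "") {
    stop("no python interpreter found; install RDKit ",
         "(e.g. conda install -c conda-forge rdkit) to use SMILES input")
  }
  probe <- suppressWarnings(system2(
    python, c("-c", shQuote("import rdkit")), stdout = FALSE, stderr = FALSE))
  if (probe != 0) {
    stop("RDKit not importable from '", python, "'; install it ",
         "(e.g. conda install -c conda-forge rdkit) to use SMILES input")
  }
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "from rdkit.Chem import MACCSkeys",
    "for line in sys.stdin:",
    "    did, smi = line.rstrip('\\n').split('\\t')",
    "    mol = Chem.MolFromSmiles(smi)",
    "    if mol is None:",  # rdkit logs noise on stderr; flag id on stdout
    "        sys.stdout.write('UNPARSEABLE\\t' + did + '\\n'); sys.exit(3)",
    "    bits = MACCSkeys.GenMACCSKeys(mol).ToBitString()[1:]",  # drop bit 0
    "    sys.stdout.write(did + '\\t' + bits + '\\n')",
    sep = "\n")
  inp <- tempfile()
  writeLines(paste(names(smiles), smiles, sep = "\t"), inp)
  out <- tempfile()
  err <- tempfile()
  status <- suppressWarnings(system2(python, c("-c", shQuote(script)),
                                     stdin = inp, stdout = out, stderr = err))
  if (status == 3) {
    last <- utils::tail(readLines(out, warn = FALSE), 1)
    stop("unparseable SMILES for drug '",
         sub("^UNPARSEABLE\t", "", last), "'")
  }
  if (status != 0) {
    stop("fingerprint helper failed: ", paste(readLines(err), collapse = " "))
  }
  read_fingerprints(out, length = 166L)
}
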