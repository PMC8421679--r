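#' Read a binary drug-target adjacency matrix
#'
#' Reads the tab-separated matrix dialect used by the Yamanishi gold-standard
#' DTI benchmarks: a header row of column identifiers, a leading label column
#' of row identifiers, and a body of 0/1 cells. The benchmark distribution
#' places targets on rows and drugs on columns, but both layouts occur in the
#' wild, so the orientation can be stated or auto-detected.
#'
#' @param path Path to a TSV adjacency file.
#' @param orientation One of `"auto"`, `"drugs_as_columns"`,
#'   `"drugs_as_rows"`. Under `"auto"`, identifiers starting with `"D"` are
#'   taken as drugs and identifiers starting with `"hsa"` as targets
#'   (the KEGG conventions of the benchmark files); if neither prefix rule
#'   fires, the reader falls back to drugs-as-columns with a warning.
#' @return An `interaction_matrix`: list with `drug_ids`, `target_ids`, and
#'   the m x n binary matrix `Y` (drugs on rows).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("\tD1\tD2", "hsa:10\t1\t0", "hsa:20\t0\t1"), f)
#' im <- read_interactions(f)
#' dim(im$Y) # 2 drugs x 2 targets
#' @export
read_interactions <- function(path,
                              orientation = c("auto", "drugs_as_columns",
                                              "drugs_as_rows")) {
  orientation <- match.arg(orientation)
  tab <- read_labeled_matrix(path)
  M <- tab$M
  storage.mode(M) <- "double"
  bad <- which(!(M %in% c(0, 1)) | is.na(M), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-binary cell at row '", tab$row_ids[bad[1, 1]], "', column '",
         tab$col_ids[bad[1, 2]], "' in ", path)
  }

  if (orientation == "auto") {
    rows_drug <- prefix_vote(tab$row_ids)
    cols_drug <- prefix_vote(tab$col_ids)
    orientation <- if (identical(rows_drug, TRUE) ||
                       identical(cols_drug, FALSE)) {
      "drugs_as_rows"
    } else if (identical(cols_drug, TRUE) || identical(rows_drug, FALSE)) {
      "drugs_as_columns"
    } else {
      warning("cannot infer orientation from identifier prefixes in ", path,
              "; assuming drugs are on columns")
      "drugs_as_columns"
    }
  }

  if (orientation == "drugs_as_columns") {
    interaction_matrix(drug_ids = tab$col_ids, target_ids = tab$row_ids,
                       Y = t(M))
  } else {
    interaction_matrix(drug_ids = tab$row_ids, target_ids = tab$col_ids,
                       Y = M)
  }
}

# TRUE if ids look like drugs (KEGG "D..."), FALSE if like targets
# ("hsa..."), NA if ambiguous.
prefix_vote <- function(ids) {
  if (all(grepl("^D", ids))) return(TRUE)
  if (all(grepl("^hsa", ids))) return(FALSE)
  NA
}

#' Construct an interaction matrix container
#'
#' @param drug_ids,target_ids Unique identifier character vectors.
#' @param Y Binary matrix, drugs on rows, targets on columns.
#' @return An `interaction_matrix` object.
#' @export
interaction_matrix <- function(drug_ids, target_ids, Y) {
  drug_ids <- as.character(drug_ids)
  target_ids <- as.character(target_ids)
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (anyDuplicated(drug_ids)) {
    stop("duplicate drug identifiers: ",
         paste(unique(drug_ids[duplicated(drug_ids)]), collapse = ", "))
  }
  if (anyDuplicated(target_ids)) {
    stop("duplicate target identifiers: ",
         paste(unique(target_ids[duplicated(target_ids)]), collapse = ", "))
  }
  if (length(drug_ids) < 1 || length(target_ids) < 1) {
    stop("need at least one drug and one target")
  }
  if (nrow(Y) != length(drug_ids) || ncol(Y) != length(target_ids)) {
    stop("Y dimensions do not match identifier lists")
  }
  if (!all(Y %in% c(0, 1))) stop("Y entries must be exactly 0 or 1")
  dimnames(Y) <- list(drug_ids, target_ids)
  structure(list(drug_ids = drug_ids, target_ids = target_ids, Y = Y),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("interaction_matrix: %d drugs x %d targets, %d interactions\n",
              length(x$drug_ids), length(x$target_ids), sum(x$Y)))
  invisible(x)
}

#' Read per-drug binary fingerprints
#'
#' Expects a two-column TSV: drug identifier, contiguous bitstring of `0`/`1`
#' characters of the declared length (166 for structural-key fingerprints).
#'
#' @param path Path to a fingerprint TSV.
#' @param length Required bitstring length.
#' @return A `fingerprint_set`: list with `drug_ids` and the binary matrix
#'   `bits` (drugs on rows, `length` columns).
#' @export
read_fingerprints <- function(path, length = 166L) {
  length <- as.integer(length)
  if (length < 1) stop("fingerprint length must be >= 1")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!base::length(lines)) stop("empty fingerprint file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 2)) {
    stop("line ", which(nfield != 2)[1], " of ", path,
         " does not have exactly 2 tab-separated fields")
  }
  ids <- vapply(parts, `[[`, "", 1)
  strs <- vapply(parts, `[[`, "", 2)
  bad <- which(nchar(strs) != length | grepl("[^01]", strs))
  if (base::length(bad)) {
    stop("invalid fingerprint for drug '", ids[bad[1]], "': expected ",
         length, " characters of {0,1}, got '",
         substr(strs[bad[1]], 1, 20), "...' (length ",
         nchar(strs[bad[1]]), ")")
  }
  bits <- matrix(0, nrow = base::length(ids), ncol = length)
  for (i in seq_along(strs)) {
    bits[i, ] <- as.integer(strsplit(strs[i], "", fixed = TRUE)[[1]])
  }
  fingerprint_set(ids, bits)
}

#' Construct a fingerprint set container
#' @param drug_ids Unique identifiers.
#' @param bits Binary matrix, one fingerprint per row.
#' @return A `fingerprint_set` object.
#' @export
fingerprint_set <- function(drug_ids, bits) {
  drug_ids <- as.character(drug_ids)
  bits <- as.matrix(bits)
  storage.mode(bits) <- "double"
  if (anyDuplicated(drug_ids)) {
    stop("duplicate drug identifiers in fingerprint set")
  }
  if (nrow(bits) != length(drug_ids)) stop("one fingerprint per drug required")
  if (ncol(bits) < 1) stop("fingerprint length must be >= 1")
  if (!all(bits %in% c(0, 1))) stop("fingerprint bits must be 0 or 1")
  rownames(bits) <- drug_ids
  structure(list(drug_ids = drug_ids, bits = bits), class = "fingerprint_set")
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat(sprintf("fingerprint_set: %d drugs, %d bits each\n",
              length(x$drug_ids), ncol(x$bits)))
  invisible(x)
}

#' Read target-disease associations from an edge list
#'
#' One `(target_id, disease_id)` pair per line, tab-separated. Duplicate
#' edges collapse to a single association.
#'
#' @param path Path to the edge-list TSV.
#' @return A `disease_profiles` object: `target_ids`, `disease_ids`, and the
#'   binary association matrix `P` (targets on rows).
#' @export
read_target_disease <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty target-disease file (no diseases): ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 2)) {
    stop("line ", which(nfield != 2)[1], " of ", path,
         " does not have exactly 2 tab-separated fields")
  }
  targets <- vapply(parts, `[[`, "", 1)
  diseases <- vapply(parts, `[[`, "", 2)
  tid <- unique(targets)
  did <- unique(diseases)
  P <- matrix(0, nrow = length(tid), ncol = length(did),
              dimnames = list(tid, did))
  P[cbind(match(targets, tid), match(diseases, did))] <- 1
  disease_profiles(tid, did, P)
}

#' Construct a target-disease profile container
#' @param target_ids,disease_ids Unique identifiers.
#' @param P Binary matrix, targets on rows, diseases on columns.
#' @return A `disease_profiles` object.
#' @export
disease_profiles <- function(target_ids, disease_ids, P) {
  target_ids <- as.character(target_ids)
  disease_ids <- as.character(disease_ids)
  P <- as.matrix(P)
  storage.mode(P) <- "double"
  if (anyDuplicated(target_ids) || anyDuplicated(disease_ids)) {
    stop("duplicate identifiers in disease profiles")
  }
  if (!all(P %in% c(0, 1))) stop("association entries must be 0 or 1")
  if (nrow(P) != length(target_ids) || ncol(P) != length(disease_ids)) {
    stop("P dimensions do not match identifier lists")
  }
  dimnames(P) <- list(target_ids, disease_ids)
  structure(list(target_ids = target_ids, disease_ids = disease_ids, P = P),
            class = "disease_profiles")
}

#' @export
print.disease_profiles <- function(x, ...) {
  cat(sprintf("disease_profiles: %d targets x %d diseases, %d associations\n",
              length(x$target_ids), length(x$disease_ids), sum(x$P)))
  invisible(x)
}

#' Write / read a similarity matrix as TSV
#'
#' The on-disk form is a square labeled matrix: header row of identifiers,
#' label column of the same identifiers in the same order, values printed
#' with 17 significant digits so a write/read round trip is lossless to
#' better than 1e-12.
#'
#' @param sim A `similarity_matrix`.
#' @param path Output path.
#' @return `write_similarity` returns `path` invisibly; `read_similarity`
#'   returns a `similarity_matrix`.
#' @export
write_similarity <- function(sim, path) {
  stopifnot(inherits(sim, "similarity_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", sim$ids), collapse = "\t"), con)
  body <- apply(sim$S, 1, function(r) {
    paste(formatC(r, digits = 17, format = "g"), collapse = "\t")
  })
  writeLines(paste(sim$ids, body, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_similarity
#' @param path Path of a TSV written by `write_similarity`.
#' @export
read_similarity <- function(path) {
  tab <- read_labeled_matrix(path)
  if (!identical(tab$row_ids, tab$col_ids)) {
    stop("similarity file is not square with matching identifiers: ", path)
  }
  M <- tab$M
  storage.mode(M) <- "double"
  if (anyNA(M)) stop("non-numeric value in similarity file: ", path)
  similarity_matrix(tab$row_ids, M)
}

#' Write predictions as a three-column TSV
#'
#' @param pred Data frame with columns `drug_id`, `target_id`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path) {
  stopifnot(all(c("drug_id", "target_id", "score") %in% names(pred)))
  utils::write.table(pred[, c("drug_id", "target_id", "score")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Persist / restore a trained cascade model
#'
#' The container is a single file embedding a format-version string; a file
#' written by a future incompatible version is refused rather than
#' misinterpreted.
#'
#' @param model A `cascade_model`.
#' @param path Output path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cascade_model"))
  container <- list(format = "thncdf-model", format_version = "1",
                    model = model)
  saveRDS(container, path, version = 2)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  container <- readRDS(path)
  if (!identical(container$format, "thncdf-model")) {
    stop("not a model container: ", path)
  }
  if (!identical(container$format_version, "1")) {
    stop("unsupported model format version: ", container$format_version)
  }
  container$model
}

# shared low-level reader: header row + label column, ragged rows rejected
read_labeled_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("matrix file needs a header and a body: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1]]
  # tolerate both "id<TAB>..." and "<TAB>id<TAB>..." header conventions
  col_ids <- if (header[1] == "") header[-1] else {
    if (length(header) == length(parts[[2]]) - 1) header else header[-1]
  }
  ncol_body <- length(col_ids) + 1
  body <- parts[-1]
  ragged <- which(lengths(body) != ncol_body)
  if (length(ragged)) {
    stop("ragged row at line ", ragged[1] + 1, " of ", path, ": expected ",
         ncol_body, " fields, got ", lengths(body)[ragged[1]])
  }
  row_ids <- vapply(body, `[[`, "", 1)
  M <- matrix(suppressWarnings(
    as.numeric(unlist(lapply(body, `[`, -1), use.names = FALSE))),
    nrow = length(body), byrow = TRUE)
  if (anyDuplicated(row_ids)) stop("duplicate row identifier in ", path)
  if (anyDuplicated(col_ids)) stop("duplicate column identifier in ", path)
  list(row_ids = row_ids, col_ids = col_ids, M = M)
}
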