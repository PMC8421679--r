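# internal helpers: seed streams, stratified folds, config files

# Derive a child seed from a root seed and a stream index. splitmix64-style
# mixing keeps streams independent so adding a forest never reseeds earlier
# ones; result fits in a 31-bit non-negative integer for portability.
derive_seed <- function(seed, index) {
  z <- (as.double(seed) %% 2^31) + 0x9E37 * (index + 1)
  z <- (z * 2654435761) %% 2^31
  z <- (z * 40503 + index + 1) %% 2^31
  as.integer(z)
}

# Stratified fold assignment: within each class, shuffle then deal
# round-robin so fold sizes per class differ by at most one.
stratified_folds <- function(y, k, seed) {
  if (k < 2) stop("need at least 2 folds")
  y <- as.integer(y)
  if (any(table(y) < k)) {
    stop("too few members of some class for ", k,
         " folds (each fold must contain both classes)")
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Evaluate `code` under a temporary RNG state so package randomness never
# perturbs the caller's .Random.seed.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2^31))
  eval.parent(substitute(code))
}

# Parse a flat YAML-like "key: value" config file. Supports comments (#),
# blank lines, numeric/logical coercion. No nesting: the configuration
# surface is intentionally flat.
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*[:=]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: '", ln, "'")
    key <- m[2]
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) {
      num
    } else if (tolower(val) %in% c("true", "false")) {
      as.logical(toupper(val))
    } else {
      val
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
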