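# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Base-2 entropy of a vector of counts (zeros contribute nothing).
.entropy2 <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) return(0)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

# Stratified fold assignment: integer vector of fold ids in 1..k, each
# class spread as evenly as possible across folds. Deterministic in seed.
.stratified_folds <- function(classes, k, seed) {
  n <- length(classes)
  if (k > n) stop("more folds than samples")
  folds <- integer(n)
  .with_seed(seed, {
    offset <- 0L   # rotate across classes so every fold fills (incl. LOO)
    for (cl in unique(classes)) {
      idx <- which(classes == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  folds
}

# Strip an Ensembl-style version suffix (ENST00000000233.9 -> ENST00000000233).
.strip_version <- function(ids) sub("\\.[0-9]+$", "", ids)
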