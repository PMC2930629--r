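# Internal helpers shared across modules.

# Evaluate `code` with a fixed RNG seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  genv <- globalenv()
  had_seed <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a child seed below 2^31 from a base seed and stage indices.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in idx) {
    s <- (s * 48271 + as.double(i)) %% 2147483647
  }
  as.integer(s)
}

unit_norm <- function(x) {
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) return(x)
  x / nrm
}

# Column-wise Pearson correlations between matched columns of A and B.
# Columns with zero variance give 0 (no association), not NA.
paired_col_cors <- function(A, B) {
  stopifnot(ncol(A) == ncol(B), nrow(A) == nrow(B))
  Ac <- sweep(A, 2L, colMeans(A))
  Bc <- sweep(B, 2L, colMeans(B))
  num <- colSums(Ac * Bc)
  den <- sqrt(colSums(Ac^2) * colSums(Bc^2))
  out <- ifelse(den > 0, num / den, 0)
  unname(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
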