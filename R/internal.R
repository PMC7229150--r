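# Internal helpers shared across modules.

# Evaluate expr with a locally set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Pairwise Euclidean distances between the rows of two matrices.
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a * a), rowSums(b * b), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Pearson correlation that returns NA (with a note) on degenerate inputs.
safe_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])
}

# Tiny stable FNV-1a hash of a string, for config provenance.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)  # xor on the low byte
    # h * 16777619 mod 2^32 in exact double arithmetic (split at 16 bits)
    lo <- h %% 65536; hi <- h %/% 65536
    h <- ((lo * 16777619) %% 4294967296 +
            ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
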