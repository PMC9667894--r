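# Internal helpers: seed scoping, numerics.

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seeds so replicate r is reproducible regardless of
# scheduling; all below 2^31.
child_seeds <- function(master, k) {
  local_seed(master, sample.int(.Machine$integer.max - 1L, k))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

# FNV-1a over a string; cheap content hash for provenance blocks.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

upper_pairs <- function(item_ids) {
  p <- length(item_ids)
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(i = idx[, 1], j = idx[, 2],
             item_a = item_ids[idx[, 1]], item_b = item_ids[idx[, 2]],
             stringsAsFactors = FALSE)
}
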