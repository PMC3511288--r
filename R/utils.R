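# Internal helpers: seeded evaluation and config hashing.

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a run seed and a stage label, staying < 2^31.
derive_seed <- function(seed, label) {
  h <- fnv1a32(charToRaw(paste0(label, ":", as.integer(seed))))
  as.integer((as.integer(seed) + h) %% 2147483647L)
}

# FNV-1a 32-bit hash over a raw vector, returned as non-negative integer.
# Done in two 16-bit halves so the multiply never exceeds double precision.
fnv1a32 <- function(raw) {
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- bitwXor32(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    # h * 16777619 mod 2^32
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  h %% 2147483647
}

bitwXor32 <- function(a, b) {
  # a may exceed .Machine$integer.max; split into halves
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

# Stable hash of an R object (used for provenance sidecars).
config_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2, xdr = TRUE)
  sprintf("%08x", fnv1a32(raw))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
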