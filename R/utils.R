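# Internal helpers: seeded randomness, hashing, numeric utilities.

# FNV-1a 32-bit hash of a raw vector, returned as a double in [0, 2^32).
# Arithmetic is done in doubles (exact for integers < 2^53).
fnv1a <- function(raw) {
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- bitwXor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# xor of two non-negative doubles interpreted as 32-bit words
bitwXor32 <- function(a, b) {
  ah <- a %/% 65536; al <- a %% 65536
  bh <- b %/% 65536; bl <- b %% 65536
  bitwXor(as.integer(ah), as.integer(bh)) * 65536 +
    bitwXor(as.integer(al), as.integer(bl))
}

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' All randomness in the package flows from a single run seed through named
#' substreams so that stages can be re-run independently without perturbing
#' each other's random draws.
#'
#' @param seed Integer master seed.
#' @param label Character label naming the substream (e.g. `"pretrain/3/12"`).
#' @return An integer in `[1, 2^31 - 2]`, suitable for [set.seed()].
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  h <- fnv1a(charToRaw(paste0(label, ":", format(seed, scientific = FALSE))))
  as.integer(h %% 2147483646) + 1L
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- get0(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Hash a configuration object
#'
#' Stable content hash used to stamp every pipeline artifact, so outputs can
#' be traced back to the exact configuration that produced them.
#'
#' @param x Any serializable R object.
#' @return An 8-character lowercase hex string.
#' @export
config_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  # skip the serialization header (R version stamps) for stability
  h <- fnv1a(raw[-seq_len(14)])
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise logsumexp of a matrix
row_logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x)))
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
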