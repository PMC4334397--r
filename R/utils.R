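# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All randomness in the package flows through this, so results are a pure
# function of the seeds handed in by the user.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive `n` child seeds from a master seed (kept below .Machine$integer.max).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# FNV-1a hash of a character scalar; used to stamp artifacts with a short
# fingerprint of the configuration that produced them.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
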