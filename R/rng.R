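#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one user-visible integer seed.
#' Independent modules (simulation, training, session replay) draw their own
#' seeds from named substreams so that, e.g., re-training a model does not
#' perturb the simulated sample. The derivation is a 32-bit FNV-1a hash of
#' `"<seed>/<stream>"`, folded into the positive 31-bit range accepted by
#' [set.seed()].
#'
#' @param seed integer master seed.
#' @param stream character scalar naming the substream.
#' @return a positive integer seed, deterministic in `(seed, stream)`.
#' @export
#' @examples
#' derive_seed(1, "simulate") != derive_seed(1, "train")
derive_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(stream),
            length(stream) == 1L)
  h <- fnv1a32(paste0(format(as.integer(seed)), "/", stream))
  # fold into [1, 2^31 - 1]
  as.integer(h %% 2147483646) + 1L
}

# FNV-1a 32-bit hash of a character scalar, returned as a double in [0, 2^32).
# Pure-R double arithmetic is exact here because every intermediate fits in
# 2^53 after the modulus.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor64(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# XOR of two nonnegative doubles < 2^32 without integer overflow.
bitwXor64 <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

#' Format a 32-bit hash as 8 hex digits
#' @param h double in `[0, 2^32)`.
#' @return character scalar.
#' @keywords internal
hash_hex <- function(h) {
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
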