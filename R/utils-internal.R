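# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic package code routes
# through this so that a single master seed makes runs bit-reproducible.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a named child seed from a master seed. Streams are decorrelated by a
# small string hash; everything stays inside the 32-bit integer range.
deriveSeed <- function(master, stream) {
  h <- 0
  for (b in utf8ToInt(stream)) h <- (h * 31 + b) %% 1013904223
  as.integer((as.numeric(master) * 69069 + h) %% .Machine$integer.max)
}

# FNV-1a hash of a character scalar, hex string. Used to stamp outputs of one
# run with a common configuration fingerprint. The 32-bit xor works on
# 16-bit halves because R's bitwXor only accepts values below 2^31.
configHash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  xor32 <- function(a, b)
    bitwXor(a %/% 65536, b %/% 65536) * 65536 + bitwXor(a %% 65536, b %% 65536)
  h <- 2166136261
  for (b in utf8ToInt(x)) h <- (xor32(h, b) * 16777619) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Round half away from zero (display convention for integer percentages).
roundHalfUp <- function(x) sign(x) * floor(abs(x) + 0.5)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

isBinary <- function(m) all(m == 0 | m == 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
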