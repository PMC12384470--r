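# Internal helpers: deterministic string hashing for per-slide RNG streams,
# and scoped seeding that restores the caller's RNG state.

# 32-bit FNV-1a over the UTF-8 bytes of a string, done in double arithmetic
# split into 16-bit halves so every intermediate stays below 2^53.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- bitwXor32(h, b)
    hi <- floor(h / 65536)
    lo <- h - hi * 65536
    h <- ((hi * p) %% 65536) * 65536 + lo * p
    h <- h %% 4294967296
  }
  h
}

# xor of a value in [0, 2^32) with a byte, in doubles
bitwXor32 <- function(h, b) {
  hi <- floor(h / 65536)
  lo <- h - hi * 65536
  hi * 65536 + bitwXor(as.integer(lo), as.integer(b))
}

# Stable per-slide seed below 2^31, derived from the master seed and the
# slide identity so regeneration is independent of generation order.
slide_seed <- function(master_seed, donor, condition, antibody, salt = "") {
  key <- paste(master_seed, donor, condition, antibody, salt, sep = "\x1f")
  as.integer(fnv1a32(key) %% 2147483647)
}

# Run code under a given seed, restoring the global RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) rlang::abort(sprintf(fmt, ...))

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    stopf("`%s` must be a finite number in [%s, %s]", name,
          format(lower), format(upper))
  }
  invisible(x)
}
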