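# Internal helpers: error signalling, seeded evaluation, stable hashing,
# half-up rounding used by the 8-bit quantizer.

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "echogel_error")))
}

abort_invalid    <- function(msg) abort(msg, "echogel_invalid_input")
abort_config     <- function(msg) abort(msg, "echogel_config_error")
abort_format     <- function(msg) abort(msg, "echogel_format_error")
abort_degenerate <- function(msg) abort(msg, "echogel_degenerate_input")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a fixed RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# FNV-1a 32-bit hash of a character string, in double arithmetic.
# Multiplication mod 2^32 is done in 16-bit halves to stay inside the
# exactly-representable integer range of doubles.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor32(h, b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536) * 65536 + lo * 16777619
    h <- h %% 4294967296
  }
  h
}

# xor of two non-negative doubles < 2^32 without 32-bit integer overflow
bitwXor32 <- function(a, b) {
  hi <- bitwXor(a %/% 65536, b %/% 65536)
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi * 65536 + lo
}

#' Derive a reproducible sub-seed from a master seed and a string key
#'
#' Stable across R sessions and platforms; adding new keys does not shift
#' the streams of existing ones. The result is always in `[1, 2^31 - 2]`.
#'
#' @param master_seed integer master seed.
#' @param key character key (e.g. `"X-silica|SC|8.5|rep2"`).
#' @return integer seed.
#' @export
derive_seed <- function(master_seed, key) {
  h <- fnv1a32(as.character(key))
  as.integer((as.double(master_seed) + h) %% 2147483646 + 1)
}

# round-half-up (quantizer contract: .5 always rounds towards +Inf)
round_half_up <- function(x) floor(x + 0.5)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
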