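# Internal utilities shared across the package.

#' Run code with a locally seeded RNG
#'
#' Saves and restores `.Random.seed` so package functions are pure functions
#' of their `seed` argument and never disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  code
}

#' Derive a stage-specific seed from a master seed
#'
#' Deterministic splitting rule so every stochastic stage of the pipeline
#' consumes its own stream derived from the single configuration seed:
#' the stage name is hashed (FNV-1a, 32-bit) and combined with the master
#' seed modulo 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param stage character stage name, e.g. `"cohort"`, `"nuisance"`.
#' @return an integer in `[0, 2^31 - 2]`.
#' @keywords internal
#' @export
split_seed <- function(seed, stage) {
  h <- fnv1a32(stage)
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

# 32-bit FNV-1a hash of a string, kept in doubles (exact below 2^53),
# reduced mod 2^31 - 1.  The per-byte XOR only touches the low 8 bits.
fnv1a32 <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(enc2utf8(x))) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- ((h %% 65536) * 16777619) %% 4294967296 +
      ((((h %/% 65536) * 16777619) %% 4294967296) * 65536) %% 4294967296
    h <- h %% 4294967296
  }
  h %% 2147483647
}

#' @noRd
upper_tri_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
warnf <- function(...) warning(sprintf(...), call. = FALSE)
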