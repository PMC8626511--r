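# Internal helpers shared across the package: border handling, seeded RNG
# isolation, and deterministic hashing for per-combination seeds.

#' Fold an index into [1, n] by boundary reflection
#'
#' Reflection does not repeat the edge sample (period `2*(n-1)`), so an
#' arbitrarily large padding amount is well defined even when the pad exceeds
#' the image extent.
#' @noRd
fold_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  j <- ((i - 1L) %% p + p) %% p
  ifelse(j < n, j + 1L, 2L * n - 1L - j)
}

#' Reflect-pad a matrix by `r` pixels on every side
#' @noRd
pad_reflect <- function(m, r) {
  stopifnot(is.matrix(m), r >= 0L)
  if (r == 0L) return(m)
  ri <- fold_index(seq.int(1L - r, nrow(m) + r), nrow(m))
  ci <- fold_index(seq.int(1L - r, ncol(m) + r), ncol(m))
  m[ri, ci, drop = FALSE]
}

#' Run an expression under a local RNG seed, restoring global RNG state
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Deterministic 31-bit string hash (for per-combination evaluation seeds)
#'
#' Plain polynomial rolling hash modulo 2^31-1; platform-independent because
#' it is carried in doubles well below 2^53.
#' @noRd
hash_string31 <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' Derive a child seed from a global seed and a label
#' @noRd
derive_seed <- function(seed, label) {
  as.integer((as.numeric(seed) * 48271 + hash_string31(label)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
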