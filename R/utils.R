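#' Derive a reproducible sub-seed from a master seed
#'
#' Mixes a master seed with one or more integer indices through a
#' multiplicative-congruential step so that every (stage, subject,
#' repetition) combination gets its own independent, stable seed. Adding
#' subjects or stages never shifts the streams of existing ones.
#'
#' @param master integer master seed.
#' @param ... integer indices identifying the stage / subject / repetition.
#' @return A single integer seed in [0, 2^31 - 2].
#' @examples
#' deriveSeed(1, 101, 3)
#' @export
deriveSeed <- function(master, ...) {
  ix <- c(...)
  x <- as.double(master) %% 2147483647
  for (i in ix) x <- (x * 69069 + as.double(i)) %% 2147483647
  as.integer(x)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL evaluates expr with the ambient RNG untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# symmetric upper-triangle pair index table (i < j), row-major order
pairIndex <- function(n) {
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
}

stopifnot2 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
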