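# Internal numeric and RNG helpers shared across the package.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs \code{expr} with the global RNG seeded to \code{seed} and restores the
#' previous \code{.Random.seed} afterwards, so library calls never perturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# Row-wise softmax of a matrix of scores; numerically stabilised.
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log softmax of a vector
log_softmax <- function(x) x - logsumexp(x)

# Derive a stream seed from a base seed; keeps results independent across
# named uses of the same base seed while staying inside 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 1000003L + as.integer(offset)) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
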