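#' Evaluate an expression under a local RNG seed
#'
#' Runs \code{expr} with the global RNG seeded to \code{seed} and restores the
#' previous RNG state afterwards, so seeded stages do not perturb the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
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

#' Derive a stage seed from a global seed
#'
#' Stable, collision-resistant-enough mapping from (global seed, stage name)
#' to a 31-bit seed, so every stochastic pipeline stage has its own
#' reproducible stream.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed in [0, 2^31).
#' @export
stageSeed <- function(seed, stage) {
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

# clamp to [lo, hi]
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# largest-remainder rounding of n * fractions to integers summing to n
largestRemainder <- function(n, fractions) {
  quota <- n * fractions
  base <- floor(quota)
  seats <- round(n - sum(base))
  if (seats > 0) {
    rem <- quota - base
    take <- order(rem, decreasing = TRUE)[seq_len(seats)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}
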