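# Internal helpers shared across modules.

#' Derive a reproducible child seed from a parent seed and integer keys
#'
#' All stochastic components (synthetic rendering, augmentation, shuffling,
#' weight initialisation) draw their seeds through this mixer so that
#' generation order never changes content: sample k of leaf j always sees the
#' same stream regardless of how many samples were drawn before it.
#'
#' @param seed parent seed (non-negative integer).
#' @param ... integer keys identifying the consumer (e.g. leaf id, sample
#'   index, epoch number).
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, ...) {
  keys <- c(seed, ...)
  h <- 104729
  for (k in keys) {
    # all intermediates stay far below 2^53, so double arithmetic is exact
    h <- (h * 33 + (as.numeric(k) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards.
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# zero-padded integer labels so that lexicographic order equals numeric order
padId <- function(i, n) {
  formatC(i, width = max(1L, nchar(as.character(max(n - 1L, 0L)))), flag = "0")
}

# locale-independent (C collation) sort, used wherever ids are assigned from
# display names
csort <- function(x) sort(x, method = "radix")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
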