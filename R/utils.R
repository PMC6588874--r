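# Internal helpers shared across modules.

#' @importFrom stats median pf phyper pnbinom pt rbinom rnbinom rnorm runif
#'   setNames cor sd var quantile p.adjust dnbinom dpois rlnorm
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
# All generator randomness is funnelled through this so that a single
# config seed makes every emitted file reproducible.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a per-stage sub-seed from a master seed; keeps results < 2^31.
sub_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483647L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
msgf  <- function(fmt, ...) message(sprintf(fmt, ...))

assert_that <- function(cond, fmt, ...) if (!isTRUE(cond)) stopf(fmt, ...)

#' Percentage of a count over a total
#'
#' Report-level percentages are always recomputed from counts with this
#' helper (never stored independently), rounded to `digits` decimals.
#'
#' @param x count
#' @param total denominator count
#' @param digits decimal places (default 1)
#' @return numeric percentage
#' @export
pct <- function(x, total, digits = 1) {
  if (total == 0) return(NA_real_)
  round(100 * x / total, digits)
}
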