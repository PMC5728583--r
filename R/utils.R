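#' Round half away from zero
#'
#' Commercial rounding to a whole number: 59.5 becomes 60, -0.5 becomes
#' -1. Used for dissimilarity percentages and capture fractions instead
#' of base R's round-half-to-even.
#'
#' @param x numeric vector.
#' @return numeric vector of integers.
#' @export
roundHalfUp <- function(x) sign(x) * floor(abs(x) + 0.5)

## Evaluate 'code' under set.seed(seed) without disturbing the caller's
## RNG stream; seed = NULL leaves the stream untouched.
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

## Short stable hash of a configuration list (no external digest
## dependency): polynomial rolling hash over the deparsed value, kept
## inside 31 bits.
.configHash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
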