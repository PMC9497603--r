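#' @keywords internal
"_PACKAGE"

## Seed plumbing. Every stochastic operation takes an explicit integer seed
## and leaves the caller's RNG stream untouched.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
  }
  force(code)
}

#' Derive a child seed from a master seed and a label
#'
#' Deterministic seed splitting: each named sub-stream of a computation
#' (covariate draw, coefficient draw, network initialization, ...) gets its
#' own child seed so that components can be re-run or shared independently.
#' The scheme is a multiplicative congruential hash of the label folded into
#' the master seed, reduced modulo 2^31 - 1 so the result is a valid R seed.
#'
#' @param seed master integer seed.
#' @param tag character label naming the sub-stream.
#' @return an integer in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  m <- 2147483647  # 2^31 - 1
  h <- (as.numeric(seed) %% m)
  for (k in utf8ToInt(tag)) {
    h <- (h * 69069 + k) %% m
  }
  as.integer(h)
}

stop_invalid <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "nnaipw_error")))
}
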