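# RNG plumbing: every stochastic entry point takes an explicit seed, uses a
# local RNG scope (the caller's .Random.seed is restored on exit), and
# derives named substreams deterministically from one root seed.

#' @keywords internal
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  old
}

#' @keywords internal
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Derive a named substream seed from a root seed
#'
#' Deterministic 31-bit hash of `(root, name)`; used to split one root seed
#' into independent streams (e.g. GA / PSO / simulator / images).
#'
#' @param root integer root seed.
#' @param name character stream name.
#' @return A single integer in `[0, 2^31 - 1]`.
#' @export
substream_seed <- function(root, name) {
  h <- as.integer(root) %% 2147483647
  for (ch in utf8ToInt(name)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate an expression under a temporary RNG seed
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  expr
}

# Clip a numeric vector into box bounds.
clip_box <- function(x, lower, upper) pmin(pmax(x, lower), upper)
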