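#' Derive a child seed from a global seed and a component name
#'
#' All randomness in the package flows from one global seed. Each stage or
#' generator derives its own seed as
#' `(seed * 48271 + h(component)) mod (2^31 - 1)` where `h` is the sum of the
#' component name's UTF-8 codes weighted by position. The derivation is fixed
#' so that any stage can be re-run in isolation and reproduce the full-run
#' output.
#'
#' @param seed integer global seed.
#' @param component character scalar naming the consumer (e.g. "impute",
#'   "fiber_map/iNM/2").
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, component) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(component),
            length(component) == 1L)
  codes <- utf8ToInt(component)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  # doubles are exact here: (2^31-1)*48271 + h < 2^53
  as.integer(((abs(seed) %% 2147483647) * 48271 + h * 7919) %% 2147483647)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so library code does not disturb the
#' caller's RNG stream.
#'
#' @param seed integer seed, or NULL to leave the RNG alone.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# fixed-precision numeric formatting used by every writer, so that output
# checksums are stable across platforms
format_num <- function(x, digits = 10L) {
  ifelse(is.na(x), "", sprintf(paste0("%.", digits, "g"), x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
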