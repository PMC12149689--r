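#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package internals
#' (phantom rendering, training data order, weight init) never disturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream id, kept < 2^31.
# Double arithmetic: the product stays exactly representable (< 2^53)
# and avoids integer overflow for large base seeds.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1103 + as.numeric(stream) * 12289) %%
               2147483647)
}

abort_validation <- function(msg) {
  stop(structure(
    class = c("echoqc_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_validation(sprintf("`%s` must be a single non-missing number", name))
  }
}
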