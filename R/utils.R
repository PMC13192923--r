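#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) if (!isTRUE(cond)) stopf(...)

# Derive a stage-specific seed from a global seed; keeps stages isolated
# under reruns while staying inside the 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% .Machine$integer.max)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}
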