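# Internal helpers shared across modules.

# Run `expr` with the RNG seeded at `seed`, restoring the caller's RNG state
# afterwards.  seed = NULL means "consume the current stream" (used by rots()
# which seeds once and draws plans in a documented order).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(sprintf(...))
}
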