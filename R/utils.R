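#' @keywords internal
"_PACKAGE"

## Run an expression under a fixed RNG seed, restoring the caller's RNG state.
## Keeps every seeded operation local so that library code never perturbs the
## user's random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

## Derive a reproducible 32-bit sub-seed from a base seed and an index,
## so that per-iteration draws are independent but replayable.
derive_seed <- function(seed, i) {
  (as.double(seed) * 48271 + as.double(i) * 16807) %% 2147483647
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_integerish <- function(x, tol = 1e-8) {
  all(is.finite(x)) && max(abs(x - round(x))) <= tol
}
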