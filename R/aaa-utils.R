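#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run an expression under a local RNG state; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## Derive a stream-specific child seed from a master seed (kept < 2^31).
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483629)
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-300) stopf("cannot normalize a zero vector")
  v / n
}
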