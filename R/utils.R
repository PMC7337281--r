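#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Classed errors so callers can distinguish validation / design / numeric
## failures programmatically.
stop_rflb <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "rflb_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

## Evaluate `code` under a fixed RNG state without clobbering the caller's
## stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

## Deterministic sub-seed derivation; stays below 2^31 - 1.
derive_seed <- function(seed, k) {
  v <- ((as.numeric(seed) %% 2147483629) * 7919 + 104729 * as.numeric(k))
  as.integer(v %% 2147483629) + 1L
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x, open = TRUE) {
  length(x) == 1L && is.numeric(x) && is.finite(x) &&
    if (open) (x > 0 && x < 1) else (x >= 0 && x <= 1)
}
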