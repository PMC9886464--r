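# Internal helpers: classed conditions and seeded RNG scoping.

abort_validation <- function(msg, ...) {
  stop(structure(
    class = c("pcgdx_validation_error", "pcgdx_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

abort_degenerate <- function(msg, ...) {
  stop(structure(
    class = c("pcgdx_degenerate_error", "pcgdx_validation_error",
              "pcgdx_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

abort_io <- function(msg, ...) {
  stop(structure(
    class = c("pcgdx_io_error", "pcgdx_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state (global .Random.seed is restored on exit).
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-item seed derived from a master seed; kept < 2^31.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Half-up rounding to `digits` decimals (display convention for metric tables).
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  trunc(x * f + sign(x) * 0.5 + sign(x) * .Machine$double.eps * abs(x) * f) / f
}
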