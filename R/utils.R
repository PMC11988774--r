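# Internal helpers shared across modules.

#' @keywords internal
stop_with <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "proxcaries_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

stop_invalid_geometry <- function(msg) stop_with(msg, "proxcaries_invalid_geometry")
stop_format <- function(msg) stop_with(msg, "proxcaries_format_error")
stop_usage <- function(msg) stop_with(msg, "proxcaries_usage_error")

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#' @keywords internal
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a per-item 32-bit seed from a base seed and an index; exact in
# double arithmetic (all intermediates < 2^53).
derive_seed <- function(seed, index) {
  as.integer((abs(seed) * 1000003 + abs(index) * 7919) %% 2147483629)
}
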