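#' @keywords internal
"_PACKAGE"

# Clamp to [lo, hi]. Values already inside the range pass through unchanged
# (bit-exact), which is what makes the lambda = 0 transform an exact identity.
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

stop_pseudonir <- function(..., class) {
  stop(structure(
    class = c(class, "pseudonir_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_that <- function(cond, ..., class = "pseudonir_input_error") {
  if (!isTRUE(cond)) stop_pseudonir(..., class = class)
  invisible(TRUE)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
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

# Derive a stream of child seeds from one master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
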