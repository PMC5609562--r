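# Internal helpers shared across modules.

#' @keywords internal
sigmoid <- function(x, slope = 1, offset = 0) {
  1 / (1 + exp(-(slope * (x - offset))))
}

# Run `code` under a fixed RNG seed and restore the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic derivation of per-epoch / per-subject seeds from a master
# seed: a small multiplicative hash kept inside 32-bit integer range.
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 7919 + as.numeric(index) * 104729 + 17) %%
               2147483587)
}

stop_input <- function(...) stop(..., call. = FALSE)

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_input(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}
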