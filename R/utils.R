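# internal helpers shared across modules

TREATMENTS <- c("Rc", "Rg", "Dc", "Dg")

#' @noRd
shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# sample SD (n - 1); NA for a single value
#' @noRd
sd_sample <- function(x) stats::sd(x)

# deterministic sub-seed derivation; keeps results reproducible when parts of
# a run are regenerated in isolation.  Stays within 32-bit integer range.
#' @noRd
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000000L) * 2011L + as.integer(stream) * 7919L
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}
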