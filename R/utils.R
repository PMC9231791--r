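# internal helpers shared across modules

# derive a reproducible child seed from a master seed and a counter;
# kept below 2^31 - 1 so it is always a valid R integer seed
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 9176) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  invisible(x)
}
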