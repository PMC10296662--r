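# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  assert_that(is.numeric(x) && length(x) == 1L && is.finite(x),
              sprintf("`%s` must be a single finite number", name))
  if (positive) assert_that(x > 0, sprintf("`%s` must be > 0", name))
  if (nonneg)  assert_that(x >= 0, sprintf("`%s` must be >= 0", name))
  invisible(TRUE)
}

assert_seed <- function(seed, name = "seed") {
  assert_that(is.numeric(seed) && length(seed) == 1L && is.finite(seed) &&
                seed == round(seed),
              sprintf("`%s` must be a single integer", name))
  invisible(as.integer(seed))
}

# Deterministic child-seed derivation; stays within 32-bit integer range.
derive_seed <- function(seed, k) {
  s <- (abs(as.numeric(seed)) * 48271 + as.numeric(k) * 16807 + 12345) %%
    2147483629
  as.integer(s)
}
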