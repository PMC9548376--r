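#' @keywords internal
"_PACKAGE"

# Validation helper: stop with the caller-facing message when cond is FALSE.
check <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

check_scalar_pos <- function(x, name) {
  check(is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0,
        sprintf("`%s` must be a single positive number", name))
}

check_scalar_nonneg <- function(x, name) {
  check(is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0,
        sprintf("`%s` must be a single non-negative number", name))
}

check_count <- function(x, name, min = 0L) {
  check(is.numeric(x) && length(x) == 1L && is.finite(x) &&
          x == round(x) && x >= min,
        sprintf("`%s` must be an integer >= %d", name, min))
}

check_seed <- function(seed) {
  check_count(seed, "seed")
  check(seed < 2^31, "`seed` must be below 2^31")
}

# All generator randomness is scoped: the global RNG state is untouched.
with_seed <- function(seed, code) {
  check_seed(seed)
  withr::with_seed(as.integer(seed), code)
}
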