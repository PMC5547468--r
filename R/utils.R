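# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform %||%
#' @importFrom dplyr mutate filter arrange select bind_rows group_by summarise ungroup n
#' @importFrom tibble tibble as_tibble is_tibble
NULL

# Run `expr` under a fixed RNG seed when one is supplied, leaving the caller's
# RNG state untouched; with seed = NULL the current stream is used (and
# advanced), so explicit seeds remain the reproducibility contract.
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::with_seed(as.integer(seed), expr)
  }
}

# Derive a child seed from a parent seed so that sub-operations of a seeded
# pipeline get distinct but reproducible streams. Kept below 2^31 - 1.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 48271 + 1009L * as.integer(k)) %% 2147483562L
}

assert_scalar_prob <- function(x, name, allow_one = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      (if (allow_one) x > 1 else x >= 1)) {
    abort(sprintf("`%s` must be a single number in [0, %s).",
                  name, if (allow_one) "1]" else "1"))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %s.", name, min))
  }
  invisible(as.numeric(x))
}
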