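#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

cs_abort <- function(..., call. = FALSE) {
  stop(sprintf(...), call. = call.)
}

cs_assert <- function(cond, ...) {
  if (!isTRUE(cond)) cs_abort(...)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' Derive a stage-specific random seed from a global seed
#'
#' A counter-based derivation so that inserting or dropping a pipeline stage
#' does not perturb the random draws of the other stages. Seeds stay within
#' the 32-bit integer range expected by [set.seed()].
#'
#' @param seed Global integer seed.
#' @param counter Non-negative integer identifying the consumer (stage index,
#'   replicate number, ...).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, counter) {
  cs_assert(is_count(seed, min = 0), "seed must be a non-negative integer")
  cs_assert(is_count(counter, min = 0), "counter must be a non-negative integer")
  # splitmix-style integer mix, folded into [0, 2^31 - 1]
  x <- (as.double(seed) * 2654435761 + as.double(counter) * 40503 + 12345) %% 2147483647
  as.integer(x)
}

# quantile type 7 quartiles as a named vector
quartiles <- function(x) {
  q <- stats::quantile(x, probs = c(0.25, 0.75), names = FALSE)
  c(q1 = q[1], q3 = q[2])
}
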