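## Internal helpers.

# Deterministic sub-stream seed: stages of a pipeline each reseed from the
# root seed so they can be re-run in isolation. Kept below 2^31 - 1.
childSeed <- function(seed, k) {
  (as.numeric(seed) * 1000003 + 97 * k) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_prob <- function(x, name, open0 = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1 ||
      (open0 && x == 0))
    stop(sprintf("'%s' must be a single value in %s0, 1]", name,
                 if (open0) "(" else "["), call. = FALSE)
  invisible(x)
}

# Convert a haplotype matrix (2 rows per animal) to a dosage matrix.
haploToDosage <- function(h) {
  odd <- seq(1L, nrow(h), by = 2L)
  h[odd, , drop = FALSE] + h[odd + 1L, , drop = FALSE]
}
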