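# Internal helpers shared across modules.

# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched, so every exported operation is a pure function
# of its declared seed.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
              rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Largest-remainder apportionment of n items into partitions with the given
# fractions; ties (and leftover seats with equal remainders) go to the
# earlier partition, so train is favoured with the conventional ordering.
largestRemainder <- function(n, fractions) {
  stopifnot(all(fractions >= 0), abs(sum(fractions) - 1) < 1e-9)
  quota <- n * fractions
  sizes <- floor(quota)
  left <- n - sum(sizes)
  if (left > 0) {
    rem <- quota - sizes
    ord <- order(-rem, seq_along(fractions))
    sizes[ord[seq_len(left)]] <- sizes[ord[seq_len(left)]] + 1
  }
  as.integer(sizes)
}

# uniform validation-error helper: always names the offending field
specError <- function(field, msg) {
  stop(sprintf("%s: %s", field, msg), call. = FALSE)
}
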