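# internal helpers

# Evaluate expr with a temporarily fixed RNG state, restoring the caller's
# stream afterwards.  All package randomness flows through this.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# split a string into single characters
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# paste a character vector back into one string
collapse0 <- function(x) paste(x, collapse = "")

# derive a child seed from a base seed and a stream label, keeping the
# result a valid 32-bit integer
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k)) %% 2147483647)
}
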