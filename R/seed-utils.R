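# Seeded substreams: every stochastic step derives its own seed from the
# master seed plus a stream name, so stages are reproducible independently
# and no hidden global RNG state leaks between them.

# Deterministic 31-bit hash of a string (polynomial rolling hash).
.str_hash <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  h
}

substream_seed <- function(master_seed, stream) {
  (as.integer(master_seed) %% 2147483647L + .str_hash(stream)) %% 2147483647L
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
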