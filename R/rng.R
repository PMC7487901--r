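# Deterministic named substreams.
#
# Every scene generator draws its geometry, noise and sampling from separate
# named streams derived from the scene seed, so e.g. changing the noise level
# never reshuffles spot placement, and a pipeline stage added later never
# perturbs the randomness of earlier stages.

# Fold a (seed, name) pair into a 31-bit seed. FNV-style string hash.
.stream_seed <- function(seed, name) {
  h <- as.double(seed %% 2147483647L)
  for (b in utf8ToInt(paste0("rq:", name))) {
    h <- (h * 131 + b) %% 2147483629
  }
  as.integer(h %% 2147483647)
}

# Evaluate `expr` under the RNG stream (seed, name), restoring the caller's
# RNG state afterwards.
.with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.stream_seed(seed, name))
  expr
}
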