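# internal helpers

# Run code under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# derive a reproducible sub-seed < 2^31 from a base seed and an index
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 10007 + as.numeric(index) * 7919 + 1) %%
               2147483647)
}

log_stage <- function(fmt, ...) {
  message(sprintf(paste0("[delda] ", fmt), ...))
}
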