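# Internal helpers shared across modules.

# Run code under a deterministic RNG substream derived from (seed, offset),
# restoring the caller's RNG state afterwards. Substreams keep independently
# generated compartments (vessels, background, noise) reproducible regardless
# of evaluation order.
with_substream <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.numeric(seed) * 101L + as.numeric(offset) * 7919) %% 2147483647)
  force(code)
}

# Population (divide-by-N) variance; NA for empty input.
pop_var <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  m <- mean(x)
  mean((x - m)^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
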