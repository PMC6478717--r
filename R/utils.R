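# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All seeded generators funnel through this so that identical
# (spec, seed) pairs are bit-reproducible.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Standard logistic; rise_width is the slope scale (not the 10-90% time).
logistic <- function(t, midpoint, rise_width) {
  1 / (1 + exp(-(t - midpoint) / rise_width))
}

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
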