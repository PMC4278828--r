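#' Derive a reproducible sub-stream seed
#'
#' Monte Carlo runs draw from many logically independent random streams
#' (one per replicate, per uncertainty source, per climate variable).
#' `derive_seed()` maps a master seed plus any number of integer keys to a
#' new seed in `[1, 2^31 - 2]` through a fixed integer hash, so that any
#' single replicate (or any single noise field within a replicate) can be
#' regenerated in isolation without replaying the whole run.
#'
#' @param master integer master seed.
#' @param ... further integer keys (replicate index, variable index, ...).
#' @return A single integer seed, always in `[1, 2147483645]`.
#' @examples
#' derive_seed(42, 3, 1)
#' derive_seed(42, 3, 2) # a different, reproducible stream
#' @export
derive_seed <- function(master, ...) {
  keys <- c(...)
  stopifnot(length(master) == 1L, is.finite(master))
  h <- abs(as.numeric(master)) %% 2147483647
  for (k in c(0, as.numeric(keys))) {
    # two LCG-style mixing rounds; multipliers small enough that every
    # product stays below 2^53, so double arithmetic is exact
    h <- (h * 69069 + abs(k) %% 2147483647 + 1) %% 2147483647
    h <- (h * 40692 + 3) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. All stochastic operations in the package funnel through
# this so repeated calls with the same seed are bit-identical.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
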