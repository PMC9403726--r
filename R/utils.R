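# seed plumbing: a single master seed deterministically derives per-stage /
# per-restart / per-cohort seeds, all kept inside 32-bit integer range

#' Derive a child seed from a master seed
#'
#' Deterministic mixing of a master seed and a stream index, kept within the
#' 32-bit integer range, so stages and replicates can be re-run in isolation.
#'
#' @param seed Master integer seed.
#' @param k Stream index (integer).
#' @return Integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(k) * 7919
  as.integer(s %% 2147483645) + 1L
}

# evaluate expr under a given seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}
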