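# Seed management: all randomness flows from explicit integer seeds. Helpers
# run seeded code without disturbing the caller's RNG state, and derive
# per-item child seeds from a corpus seed so corpora regenerate piecewise.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive reproducible child seeds from one seed
#'
#' @param seed Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of `n` seeds in \[1, 2^31 - 2\].
#' @export
derive_seeds <- function(seed, n) {
  if (n == 0L) return(integer(0))
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
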