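# Seed handling: every stochastic operation takes a `seed` argument and runs
# in a private RNG scope, so package calls never disturb the caller's RNG
# stream and a master seed can spawn reproducible per-stage substreams.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Spawn reproducible sub-seeds from a master seed
#'
#' @param seed master seed (integer).
#' @param n number of sub-seeds.
#' @return Integer vector of `n` seeds, all below 2^31.
#' @export
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}
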