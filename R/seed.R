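#' Reproducible seeding
#'
#' Every stochastic generator in the package takes an explicit integer seed
#' and is a pure function of (parameters, seed): the caller's random state
#' is saved and restored around each call, so generators never perturb an
#' enclosing simulation. Composite generators split their seed into stable
#' per-component sub-seeds rather than consuming a shared stream, so adding
#' a component never reshuffles the draws of the others.
#'
#' @param seed Single integer seed.
#' @param index Component index (1-based) to derive a sub-seed for.
#' @return `sub_seed()` returns a positive integer strictly below `2^31`.
#' @keywords internal
#' @name placentaq-seeding
NULL

with_local_seed <- function(seed, expr) {
  check_count(seed, "seed", lower = 0L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Weyl-sequence style mixing; keeps results in [1, 2^31 - 2] so they are
# valid arguments to set.seed() on 32-bit integer builds.
sub_seed <- function(seed, index) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.numeric(seed) %% m)
  i <- as.numeric(index)
  (s * 48271 + i * 16807 + 12345) %% (m - 1) + 1
}
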