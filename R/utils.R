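#' Derive reproducible sub-seeds from one master seed
#'
#' Layered generators (DAG sampling, latent simulation, loadings, noise)
#' each consume their own sub-seed so that a component can be regenerated
#' independently of the others while a single integer controls the whole
#' simulation.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds to derive.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(n), n >= 1)
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# off-diagonal entries of a square matrix, as a vector
offdiag <- function(m) {
  m[row(m) != col(m)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
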