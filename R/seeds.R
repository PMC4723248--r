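#' Derive child seeds from a master seed
#'
#' All generators in this package are pure functions of their parameters and
#' a single integer seed. Multi-part simulations (one seed per field, per
#' array batch, per Monte-Carlo replicate) derive child seeds from one master
#' seed through this counter scheme, so a whole run is reproducible from a
#' single integer.
#'
#' @param master integer master seed.
#' @param n number of child seeds to derive.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(n), length(n) == 1L, n >= 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}
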