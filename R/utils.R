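#' Derive a reproducible sub-seed from a master seed and a label path
#'
#' Every stochastic stage of the pipeline draws its RNG seed from the master
#' seed plus a stage label (and, where relevant, a species id), so that any
#' stage can be re-run in isolation and two runs from one configuration are
#' bit-identical.
#'
#' @param master integer master seed.
#' @param ... character or numeric labels identifying the stage.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  parts <- paste(c(master, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# run code with a local RNG state so package internals never disturb the
# caller's .Random.seed
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Fraction of a species pool, as a printed percentage
#'
#' Share of a candidate species pool that survived filtering into the
#' modelled pool, rounded to one decimal as conventionally reported.
#'
#' @param n_modelled number of species that were modelled.
#' @param n_pool size of the full candidate pool.
#' @return percentage rounded to 1 decimal place.
#' @export
pool_fraction <- function(n_modelled, n_pool) {
  stopifnot(n_pool > 0, n_modelled >= 0)
  round(100 * n_modelled / n_pool, 1)
}
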