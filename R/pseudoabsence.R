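#' Fit a surface range envelope (SRE) from presence environments
#'
#' Per-variable quantile box in environmental space: bounds are the
#' empirical `q` and `1 - q` quantiles (linear-interpolation definition,
#' [stats::quantile()] type 7) of the presence values. A cell is "inside"
#' the envelope iff every variable lies within its bounds inclusive.
#'
#' @param presence_env data.frame of presence environment values (climatic
#'   variables only).
#' @param q lower tail trimmed per side; default 0.025 (2.5%/97.5% box).
#' @return object of class `sre_envelope`: data.frame with `variable`,
#'   `lower`, `upper`, plus the `q` used.
#' @export
fit_sre <- function(presence_env, q = 0.025) {
  stopifnot(is.data.frame(presence_env))
  if (nrow(presence_env) < 2) stop("fit_sre needs >= 2 presence records")
  if (q < 0 || q >= 0.5) stop("q must satisfy 0 <= q < 0.5")
  bounds <- data.frame(
    variable = names(presence_env),
    lower = vapply(presence_env, stats::quantile, numeric(1),
                   probs = q, names = FALSE, type = 7),
    upper = vapply(presence_env, stats::quantile, numeric(1),
                   probs = 1 - q, names = FALSE, type = 7),
    row.names = NULL
  )
  structure(list(bounds = bounds, q = q), class = "sre_envelope")
}

#' Classify environments as inside/outside an SRE
#'
#' @param envelope an `sre_envelope`.
#' @param env data.frame containing at least the envelope's variables.
#' @return logical vector, `TRUE` where every variable is within its bounds
#'   (inclusive).
#' @export
sre_inside <- function(envelope, env) {
  b <- envelope$bounds
  inside <- rep(TRUE, nrow(env))
  for (i in seq_len(nrow(b))) {
    x <- env[[b$variable[i]]]
    inside <- inside & x >= b$lower[i] & x <= b$upper[i]
  }
  inside
}

#' Sample pseudo-absences outside the envelope, weighted by effort
#'
#' Draws `n` land cells without replacement from the cells outside the
#' surface range envelope, with probability proportional to the sampling
#' effort — the target-group correction, which gives the background data the
#' same spatial observation bias as the presences. Presence cells are never
#' eligible, even if they fall outside the envelope.
#'
#' @param envelope an `sre_envelope` fitted on the presences.
#' @param landscape the calibration [landscape].
#' @param effort a `sampling_effort`.
#' @param n number of pseudo-absences (by design equal to the number of
#'   presence records).
#' @param presence_cells linear cell indices of the presence records.
#' @param seed integer seed.
#' @param species_id id used in the seed derivation and the output.
#' @return list of class `pa_set`: `records` data.frame (row, col, env
#'   columns), `species_id`, `seed`.
#' @export
sample_pa <- function(envelope, landscape, effort, n, presence_cells,
                      seed = 1, species_id = "species") {
  if (n < 1) stop("n must be >= 1")
  ls <- landscape
  land_idx <- land_cells(ls)
  env <- cell_env(ls, envelope$bounds$variable, land_idx)
  eligible <- land_idx[!sre_inside(envelope, env)]
  eligible <- setdiff(eligible, presence_cells)
  if (length(eligible) < n) {
    stop(sprintf(
      paste0("only %d land cells lie outside the envelope (need %d); ",
             "reduce the SRE quantile q"),
      length(eligible), n
    ))
  }
  w <- effort$effort[eligible]
  cells <- with_seed(derive_seed(seed, "pa", species_id), {
    eligible[sample.int(length(eligible), n, replace = FALSE, prob = w)]
  })
  rec <- cbind(cell_rowcol(ls, cells), cell_env(ls, names(ls$layers), cells))
  structure(list(records = rec, species_id = species_id, seed = seed),
            class = "pa_set")
}
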