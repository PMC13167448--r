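#' Synthetic sampling-effort field
#'
#' A smooth, strictly positive effort surface over land, high near supplied
#' "collection hotspot" centres, normalized to sum to one over land. It plays
#' the role of a global sampling-effort index: presences are drawn with
#' probability proportional to suitability times effort, and pseudo-absences
#' proportional to effort (the target-group bias correction).
#'
#' @param seed integer seed (reserved; the field is deterministic in its
#'   arguments, the seed is recorded for provenance).
#' @param landscape a [landscape].
#' @param hotspot_centres list of `c(row, col)` centres; at least one must
#'   lie on land.
#' @param sigma Gaussian radius of each centre, in cells; default one eighth
#'   of the larger grid dimension.
#' @param floor_frac baseline effort everywhere, expressed as a fraction of
#'   the land-mean kernel intensity (default 0.3): even poorly collected
#'   regions of a real effort index retain some records, so the bias spans
#'   one to two orders of magnitude rather than underflowing to zero.
#'   Scaling with the kernel mean keeps the field exactly proportional
#'   under duplicated centres.
#' @return object of class `sampling_effort`: list with the effort matrix
#'   (`NA` off land, sums to 1 over land) and parameters.
#' @export
make_effort <- function(seed, landscape, hotspot_centres,
                        sigma = max(landscape$nrows, landscape$ncols) / 8,
                        floor_frac = 0.3) {
  ls <- landscape
  if (!any(ls$land)) stop("landscape has no land cells")
  if (!length(hotspot_centres)) stop("at least one hotspot centre is required")
  on_land <- vapply(hotspot_centres, function(ct) {
    isTRUE(ct[1] >= 1 && ct[1] <= ls$nrows && ct[2] >= 1 &&
             ct[2] <= ls$ncols && ls$land[ct[1], ct[2]])
  }, logical(1))
  if (!any(on_land)) stop("no hotspot centre lies inside the land mask")

  rows <- matrix(rep(seq_len(ls$nrows), ls$ncols), ls$nrows, ls$ncols)
  cols <- matrix(rep(seq_len(ls$ncols), each = ls$nrows), ls$nrows, ls$ncols)
  f <- matrix(0, ls$nrows, ls$ncols)
  for (ct in hotspot_centres) {
    d2 <- (rows - ct[1])^2 + (cols - ct[2])^2
    f <- f + exp(-d2 / (2 * sigma^2))
  }
  f[!ls$land] <- NA_real_
  f[ls$land] <- f[ls$land] + floor_frac * mean(f[ls$land])
  total <- sum(f[ls$land])
  if (!is.finite(total) || total <= 0) stop("degenerate effort field")
  f[ls$land] <- f[ls$land] / total
  structure(
    list(effort = f, centres = hotspot_centres, sigma = sigma,
         floor_frac = floor_frac, seed = seed),
    class = "sampling_effort"
  )
}

#' Default niche configuration for virtual species
#'
#' Virtual species respond to all four climatic layers of predictor set 1,
#' so the climatic range envelope used for pseudo-absence placement is
#' coherent with the true niche (a species indifferent to one of the
#' screened climate axes would receive pseudo-absences in perfectly
#' suitable cells, which no real flora exhibits at this severity). Niche
#' optima are drawn between the 15% and 85% land quantiles of each layer
#' (optima sit inside, not at the edge of, the available climate), and
#' per-axis niche breadths between 0.6 and 1.2 land standard deviations —
#' with four multiplicative axes this yields moderate specialists whose
#' occurrence data carry the strong climatic signal of the modelled
#' naturalized flora.
#'
#' @return named list of niche-generation parameters.
#' @export
default_niche_config <- function() {
  list(
    variables = c("temp_mean", "temp_range", "precip_annual",
                  "precip_seasonality"),
    mu_quantiles = c(0.15, 0.85),
    sigma_sd_range = c(0.6, 1.2),
    lambda = 500,           # expected raw occurrence records per species
    error_rate = 0.02,      # share of suitability-independent records
    max_continents = 2L     # naturalized-continent sets hold 1..max labels
  )
}

#' Generate virtual species with known Gaussian niches
#'
#' Each species' true suitability is a product of independent Gaussian
#' responses over the configured niche variables,
#' `S*(cell) = prod_v exp(-(x_v - mu_v)^2 / (2 sigma_v^2))`, rescaled so its
#' maximum over land is 1. Each species is also assigned a non-empty set of
#' continents where it is "already naturalized" (used by the dispersal
#' sensitivity filter).
#'
#' @param seed integer seed.
#' @param landscape the current-scenario [landscape].
#' @param n_species number of species to generate.
#' @param niche_config list as in [default_niche_config()].
#' @return list of `virtual_species` objects: `id`, `niche` (data.frame with
#'   `variable`, `mu`, `sigma`), `suitability` matrix (max 1 on land, `NA`
#'   off land), `continents`, `lambda`.
#' @export
make_species <- function(seed, landscape, n_species,
                         niche_config = default_niche_config()) {
  ls <- landscape
  cfg <- niche_config
  bad <- setdiff(cfg$variables, names(ls$layers))
  if (length(bad)) {
    stop("niche variable(s) not a landscape layer: ", paste(bad, collapse = ", "))
  }
  if (length(cfg$variables) < 2) stop("niche_config must name >= 2 layers")
  land_idx <- land_cells(ls)
  n_cont <- length(unique(ls$continent[land_idx]))
  env <- cell_env(ls, cfg$variables, land_idx)
  qs <- lapply(env, stats::quantile, probs = cfg$mu_quantiles, names = FALSE)
  sds <- lapply(env, stats::sd)

  lapply(seq_len(n_species), function(i) {
    id <- sprintf("vs%04d", i)
    with_seed(derive_seed(seed, "species", id), {
      mu <- vapply(qs, function(q) stats::runif(1, q[1], q[2]), numeric(1))
      sigma <- vapply(sds, function(s) {
        stats::runif(1, cfg$sigma_sd_range[1] * s, cfg$sigma_sd_range[2] * s)
      }, numeric(1))
      s_land <- rep(1, length(land_idx))
      for (v in seq_along(cfg$variables)) {
        s_land <- s_land * exp(-(env[[v]] - mu[v])^2 / (2 * sigma[v]^2))
      }
      s_land <- s_land / max(s_land)
      suit <- matrix(NA_real_, ls$nrows, ls$ncols)
      suit[land_idx] <- s_land
      k <- sample(seq_len(min(cfg$max_continents, n_cont)), 1)
      structure(
        list(
          id = id,
          niche = data.frame(variable = cfg$variables, mu = mu, sigma = sigma,
                             row.names = NULL),
          suitability = suit,
          continents = sort(sample(seq_len(n_cont), k)),
          lambda = cfg$lambda,
          error_rate = if (is.null(cfg$error_rate)) 0 else cfg$error_rate
        ),
        class = "virtual_species"
      )
    })
  })
}

#' Evaluate a species' true suitability on another landscape
#'
#' Applies the species' Gaussian niche to the layers of any scenario
#' landscape, keeping the rescaling constant of the current-period surface so
#' values are comparable across scenarios.
#'
#' @param species a `virtual_species`.
#' @param landscape a [landscape] (any scenario tag).
#' @return suitability matrix in `[0, 1]`-ish scale (`NA` off land).
#' @export
true_suitability <- function(species, landscape) {
  land_idx <- land_cells(landscape)
  env <- cell_env(landscape, species$niche$variable, land_idx)
  s <- rep(1, length(land_idx))
  for (v in seq_len(nrow(species$niche))) {
    s <- s * exp(-(env[[v]] - species$niche$mu[v])^2 /
                   (2 * species$niche$sigma[v]^2))
  }
  out <- matrix(NA_real_, landscape$nrows, landscape$ncols)
  out[land_idx] <- pmin(1, s / max(species$suitability, na.rm = TRUE))
  out
}

#' An occurrence set
#'
#' Presence records of one species: a data.frame of `(row, col)` cells plus
#' one column per environmental layer, with a processing-stage tag
#' (`raw`, `deduped` or `env_filtered`).
#'
#' @param records data.frame with `row`, `col` and environment columns.
#' @param species_id species identifier.
#' @param stage processing stage tag.
#' @return object of class `occurrence_set`.
#' @export
occurrence_set <- function(records, species_id, stage = "raw") {
  stopifnot(is.data.frame(records),
            all(c("row", "col") %in% names(records)) || nrow(records) == 0)
  structure(
    list(species_id = species_id, records = records, stage = stage),
    class = "occurrence_set"
  )
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set %s: %d records, stage '%s'>\n",
              x$species_id, nrow(x$records), x$stage))
  invisible(x)
}

#' Sample biased presence-only occurrence records
#'
#' Draws `N ~ Poisson(lambda)` records (with replacement, so within-cell
#' duplicates occur as in raw aggregator data) over land cells with
#' probability proportional to true suitability times sampling effort —
#' presence-only data with spatially biased observation. A small share of
#' records (`error_rate`, default 2%) is drawn proportionally to effort
#' alone, emulating the suitability-independent records (misidentified,
#' cultivated or vagrant specimens) that survive cleaning in real
#' aggregator data.
#'
#' @param seed integer seed.
#' @param species a `virtual_species`.
#' @param effort a `sampling_effort`.
#' @param landscape the [landscape] the records are observed on.
#' @return an [occurrence_set] at stage `"raw"`.
#' @export
sample_occurrences <- function(seed, species, effort, landscape) {
  ls <- landscape
  if (species$lambda <= 0) stop("lambda must be positive")
  land_idx <- land_cells(ls)
  w <- species$suitability[land_idx] * effort$effort[land_idx]
  if (all(w == 0)) stop("suitability x effort is identically zero")
  with_seed(derive_seed(seed, "occ", species$id), {
    n_raw <- stats::rpois(1, species$lambda)
    if (n_raw == 0) {
      rec <- cbind(data.frame(row = integer(), col = integer()),
                   cell_env(ls, names(ls$layers), integer()))
      return(occurrence_set(rec, species$id, "raw"))
    }
    er <- if (is.null(species$error_rate)) 0 else species$error_rate
    n_err <- stats::rbinom(1, n_raw, er)
    cells <- sample(land_idx, n_raw - n_err, replace = TRUE, prob = w)
    if (n_err > 0) {
      cells <- c(cells,
                 sample(land_idx, n_err, replace = TRUE,
                        prob = effort$effort[land_idx]))
    }
    rec <- cbind(cell_rowcol(ls, cells), cell_env(ls, names(ls$layers), cells))
    occurrence_set(rec, species$id, "raw")
  })
}
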