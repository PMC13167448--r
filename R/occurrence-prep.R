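#' Spatial deduplication of occurrence records
#'
#' Keeps exactly one record per occupied grid cell (the first in input
#' order), removing within-cell pseudoreplication.
#'
#' @param occ an [occurrence_set] at stage `"raw"`.
#' @return an [occurrence_set] at stage `"deduped"`.
#' @export
dedupe_spatial <- function(occ) {
  stopifnot(inherits(occ, "occurrence_set"))
  if (occ$stage != "raw") stop("dedupe_spatial expects stage 'raw'")
  rec <- occ$records
  keep <- !duplicated(rec[c("row", "col")])
  occurrence_set(rec[keep, , drop = FALSE], occ$species_id, "deduped")
}

#' Environmental-space thinning of occurrence records
#'
#' Builds a regular multidimensional grid over environmental space — for
#' each variable, `n_bins` equal-width bins spanning the min/max of that
#' variable over the species' own records — and retains a single record,
#' chosen uniformly at random, per occupied multidimensional bin. This
#' balances the representation of records across environmental conditions
#' and damps sampling bias towards well-collected climates.
#'
#' A variable that is constant across the records contributes a single bin.
#' The retention draw is seeded per species id, so thinning is reproducible
#' record-set by record-set.
#'
#' @param occ an [occurrence_set] at stage `"deduped"`.
#' @param layers character vector: the climatic variables of the active
#'   predictor set (see [climatic_vars()]).
#' @param n_bins bins per variable (default 6).
#' @param seed integer seed.
#' @return an [occurrence_set] at stage `"env_filtered"` (a subset of the
#'   input records).
#' @export
env_filter <- function(occ, layers, n_bins = 6, seed = 1) {
  stopifnot(inherits(occ, "occurrence_set"))
  if (occ$stage != "deduped") stop("env_filter expects stage 'deduped'")
  rec <- occ$records
  if (nrow(rec) == 0) {
    return(occurrence_set(rec, occ$species_id, "env_filtered"))
  }
  bad <- setdiff(layers, names(rec))
  if (length(bad)) stop("missing environment column(s): ",
                        paste(bad, collapse = ", "))
  bins <- vapply(layers, function(v) env_bin(rec[[v]], n_bins), integer(nrow(rec)))
  if (nrow(rec) == 1) dim(bins) <- c(1L, length(layers))
  key <- apply(bins, 1, paste, collapse = ":")
  keep <- with_seed(derive_seed(seed, "envfilter", occ$species_id), {
    vapply(split(seq_len(nrow(rec)), key), function(idx) {
      if (length(idx) == 1) idx else idx[sample.int(length(idx), 1)]
    }, integer(1))
  })
  keep <- sort(unname(keep))
  occurrence_set(rec[keep, , drop = FALSE], occ$species_id, "env_filtered")
}

# equal-width bin index over [min, max] of x; the maximum joins the top bin
# (right-closed top); constant x collapses to one bin
env_bin <- function(x, n_bins) {
  mn <- min(x)
  mx <- max(x)
  if (mx == mn) return(rep(1L, length(x)))
  b <- floor((x - mn) / (mx - mn) * n_bins) + 1L
  as.integer(pmin(b, n_bins))
}

#' Minimum-record rule
#'
#' Accepts a species for modelling only if it retains at least `threshold`
#' records after deduplication and environmental thinning; species below the
#' threshold are excluded from all downstream stages.
#'
#' @param occ an [occurrence_set] at stage `"env_filtered"`.
#' @param threshold minimum record count (default 30).
#' @return logical: `TRUE` iff the species is accepted.
#' @export
min_records_filter <- function(occ, threshold = 30) {
  stopifnot(inherits(occ, "occurrence_set"))
  if (occ$stage != "env_filtered") {
    stop("min_records_filter expects stage 'env_filtered'")
  }
  nrow(occ$records) >= threshold
}

#' Run the full occurrence-preparation chain for one species
#'
#' Fixed order: spatial dedup, then environmental thinning, then the
#' minimum-record rule.
#'
#' @param occ an [occurrence_set] at stage `"raw"`.
#' @param layers climatic variables for [env_filter()].
#' @param n_bins bins per variable.
#' @param min_records acceptance threshold.
#' @param seed integer seed.
#' @return list with elements `occ` (stage `"env_filtered"`), `accepted`,
#'   and `report` (one-row data.frame: raw_n, deduped_n, filtered_n,
#'   accepted).
#' @export
prepare_occurrences <- function(occ, layers, n_bins = 6, min_records = 30,
                                seed = 1) {
  raw_n <- nrow(occ$records)
  dd <- dedupe_spatial(occ)
  ef <- env_filter(dd, layers, n_bins = n_bins, seed = seed)
  acc <- min_records_filter(ef, threshold = min_records)
  list(
    occ = ef,
    accepted = acc,
    report = data.frame(
      species_id = occ$species_id, raw_n = raw_n, deduped_n = nrow(dd$records),
      filtered_n = nrow(ef$records), accepted = acc
    )
  )
}
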