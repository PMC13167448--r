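#' Write a landscape as a multi-page TIFF with a JSON sidecar
#'
#' One TIFF page per layer (32-bit float, values affinely rescaled to
#' `[0, 1]`), plus `<file>.json` recording layer names, per-band scale and
#' offset, the land mask, continent labels and the scenario tag, so the
#' landscape round-trips losslessly up to float precision. Off-land cells
#' are stored as 0 and restored to `NA` from the mask.
#'
#' @param ls a [landscape].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(ls, path) {
  pages <- list()
  meta_layers <- list()
  for (nm in names(ls$layers)) {
    m <- ls$layers[[nm]]
    v <- m[ls$land]
    lo <- min(v)
    hi <- max(v)
    scale <- if (hi > lo) hi - lo else 1
    pg <- (m - lo) / scale
    pg[!ls$land] <- 0
    pages[[nm]] <- pg
    meta_layers[[nm]] <- list(offset = lo, scale = scale)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    scenario = ls$scenario, seed = ls$seed,
    nrows = ls$nrows, ncols = ls$ncols,
    layers = meta_layers,
    land = which(ls$land),
    continent = as.integer(ls$continent[ls$land])
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a landscape written by [write_landscape()]
#'
#' @param path `.tif` path with its `.json` sidecar alongside.
#' @return a [landscape].
#' @export
read_landscape <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  land <- matrix(FALSE, meta$nrows, meta$ncols)
  land[meta$land] <- TRUE
  continent <- matrix(NA_integer_, meta$nrows, meta$ncols)
  continent[meta$land] <- meta$continent
  layers <- list()
  for (i in seq_along(meta$layers)) {
    nm <- names(meta$layers)[i]
    m <- pages[[i]] * meta$layers[[nm]]$scale + meta$layers[[nm]]$offset
    m[!land] <- NA_real_
    layers[[nm]] <- m
  }
  # off-land values are undefined in the file; re-mask on land only
  for (nm in names(layers)) layers[[nm]][!land] <- NA_real_
  new_landscape(meta$nrows, meta$ncols, layers, land, continent,
                meta$scenario, meta$seed)
}

#' Write occurrence (or pseudo-absence) records as CSV
#'
#' Schema: `species_id`, `row`, `col`, one column per layer value, plus an
#' optional `presence` flag column when absences are included.
#'
#' @param occ an [occurrence_set], or a data.frame already in schema.
#' @param path output CSV path.
#' @param pa optional `pa_set`; when given, rows are flagged
#'   `presence = 1/0` and both are written.
#' @return `path`, invisibly.
#' @export
write_occurrences_csv <- function(occ, path, pa = NULL) {
  df <- cbind(species_id = occ$species_id, occ$records)
  if (!is.null(pa)) {
    df$presence <- 1L
    pad <- cbind(species_id = pa$species_id, pa$records)
    pad$presence <- 0L
    df <- rbind(df, pad)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an occurrence CSV for one species
#'
#' @param path CSV path written by [write_occurrences_csv()].
#' @param stage stage tag to attach.
#' @return an [occurrence_set] (presence rows only if a flag column is
#'   present).
#' @export
read_occurrences_csv <- function(path, stage = "raw") {
  df <- utils::read.csv(path)
  if ("presence" %in% names(df)) df <- df[df$presence == 1L, ]
  sid <- unique(df$species_id)
  stopifnot(length(sid) == 1)
  df$presence <- NULL
  occurrence_set(df[setdiff(names(df), "species_id")], sid, stage)
}
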