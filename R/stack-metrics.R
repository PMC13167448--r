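#' Stack single-species binary maps into a richness raster
#'
#' Cellwise integer sum of the binary suitability maps of one ensemble
#' member: the potential number of species finding suitable conditions in
#' each cell.
#'
#' @param binary_maps list of 0/1 matrices sharing one grid (`NA` off land).
#' @return numeric richness matrix.
#' @export
stack_richness <- function(binary_maps) {
  stopifnot(length(binary_maps) >= 1)
  dims <- vapply(binary_maps, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("binary maps do not share a grid")
  }
  Reduce(`+`, binary_maps)
}

#' Invasion hotspot map at a pool-fraction cut-off
#'
#' A cell is a hotspot iff its richness strictly exceeds
#' `c = floor(f * M)`, i.e. it is suitable for more than a fraction `f` of
#' the `M` modelled species. Future maps reuse the cut-off count
#' established under current conditions by passing it as `cutoff`.
#'
#' @param richness richness matrix (`NA` off land).
#' @param M modelled species pool size.
#' @param f pool fraction (default 0.10; 0.05 / 0.15 used as sensitivity).
#' @param cutoff optional fixed cut-off count overriding `floor(f * M)`.
#' @return object of class `hotspot_result`: `M`, `f`, `cutoff`, `map`
#'   (0/1 matrix), `land_fraction`.
#' @export
hotspot_map <- function(richness, M, f = 0.10, cutoff = NULL) {
  if (M <= 0) stop("M must be positive")
  if (is.null(cutoff)) {
    if (f <= 0 || f >= 1) stop("f must be in (0, 1)")
    cutoff <- floor(f * M)
  }
  land <- !is.na(richness)
  map <- richness
  map[land] <- as.integer(richness[land] > cutoff)
  structure(
    list(M = M, f = f, cutoff = cutoff, map = map,
         land_fraction = sum(map[land]) / sum(land)),
    class = "hotspot_result"
  )
}

#' Absolute and proportional richness change maps
#'
#' @param current,future richness matrices on one grid.
#' @return list with `absolute` (`future - current`) and `proportional`
#'   (`(future - current) / current`, `NA`-masked where current is 0).
#' @export
change_maps <- function(current, future) {
  stopifnot(all(dim(current) == dim(future)))
  absolute <- future - current
  proportional <- absolute / current
  proportional[!is.na(current) & current == 0] <- NA_real_
  list(absolute = absolute, proportional = proportional)
}

#' Per-cell turnover between current and future suitable-species sets
#'
#' Default is the Jaccard dissimilarity `1 - |A n B| / |A u B|` between the
#' sets of species suitable in the cell now (`A`) and in the future (`B`):
#' 0 when the suitable species list is unchanged, 1 when not a single
#' species is shared. Cells with both sets empty score 0. The
#' `"rate"` alternative is `(gains + losses) / (|A| + gains)`, which shares
#' both endpoints.
#'
#' @param current_maps,future_maps lists of per-species 0/1 matrices (same
#'   species order and grid).
#' @param method `"jaccard"` (default) or `"rate"`.
#' @return turnover matrix in `[0, 1]` (`NA` off land).
#' @export
turnover <- function(current_maps, future_maps, method = c("jaccard", "rate")) {
  method <- match.arg(method)
  stopifnot(length(current_maps) == length(future_maps),
            length(current_maps) >= 1)
  inter <- both <- gains <- losses <- 0
  for (i in seq_along(current_maps)) {
    a <- current_maps[[i]]
    b <- future_maps[[i]]
    inter <- inter + a * b
    both <- both + pmax(a, b)
    gains <- gains + (b == 1 & a == 0)
    losses <- losses + (a == 1 & b == 0)
  }
  land <- !is.na(both)
  out <- both
  if (method == "jaccard") {
    out[land] <- ifelse(both[land] == 0, 0, 1 - inter[land] / both[land])
  } else {
    cur_n <- inter + losses
    denom <- cur_n + gains
    out[land] <- ifelse(denom[land] == 0, 0,
                        (gains[land] + losses[land]) / denom[land])
  }
  out
}

#' Coefficient-of-variation map across ensemble members
#'
#' Cellwise sample standard deviation (n - 1 denominator) of member
#' richness divided by the member mean — the spread of the prediction
#' across models, predictor sets and future realizations. Masked (`NA`)
#' where the mean is 0.
#'
#' @param member_maps list of >= 2 richness matrices.
#' @return CV matrix (`NA` off land and where mean richness is 0).
#' @export
cv_map <- function(member_maps) {
  stopifnot(length(member_maps) >= 2)
  k <- length(member_maps)
  s <- Reduce(`+`, member_maps)
  s2 <- Reduce(`+`, lapply(member_maps, function(m) m^2))
  mean_ <- s / k
  var_ <- pmax(0, (s2 - k * mean_^2) / (k - 1))
  out <- sqrt(var_) / mean_
  out[!is.na(mean_) & mean_ == 0] <- NA_real_
  out
}

#' Continent-restricted (dispersal-limited) binary map
#'
#' Zeroes predicted suitability outside the continents where the species is
#' already reported naturalized, so richness and hotspots can be
#' recomputed under the assumption that species only fill suitable areas on
#' continents they have reached.
#'
#' @param binary_map 0/1 matrix.
#' @param allowed_continents integer continent labels where the species is
#'   naturalized (non-empty).
#' @param continent integer matrix of continent labels (`NA` off land).
#' @return filtered 0/1 matrix.
#' @export
continental_filter <- function(binary_map, allowed_continents, continent) {
  if (!length(allowed_continents)) stop("empty naturalized-continent set")
  out <- binary_map
  off <- !is.na(continent) & !(continent %in% allowed_continents)
  out[off] <- 0L
  out
}

#' Fraction of current hotspots that remain hotspots
#'
#' @param current,future `hotspot_result`s on one grid with one cut-off.
#' @return percentage of current hotspot cells that are also future
#'   hotspots.
#' @export
hotspot_persistence <- function(current, future) {
  stopifnot(inherits(current, "hotspot_result"),
            inherits(future, "hotspot_result"),
            all(dim(current$map) == dim(future$map)),
            current$cutoff == future$cutoff)
  cur <- current$map == 1
  n_cur <- sum(cur, na.rm = TRUE)
  if (n_cur == 0) stop("no current hotspot cells; persistence undefined")
  100 * sum(cur & future$map == 1, na.rm = TRUE) / n_cur
}
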