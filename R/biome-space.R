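#' Load the packaged Whittaker biome polygons
#'
#' Nine biome polygons in (mean annual temperature degC, annual
#' precipitation cm) space. The vertices are a simplified synthetic
#' approximation of the classic Whittaker diagram, shipped as a versioned
#' plain-text fixture (`extdata/whittaker_biomes_synthetic.csv`): faithful
#' enough for biome bookkeeping on synthetic worlds, not a digitization of
#' any published figure.
#'
#' @return named list of polygons, each a two-column matrix
#'   (`temp_c`, `precip_cm`), ordered by biome id.
#' @export
whittaker_polygons <- function() {
  path <- system.file("extdata", "whittaker_biomes_synthetic.csv",
                      package = "invstack")
  if (path == "") stop("biome polygon fixture is missing")
  df <- utils::read.csv(path)
  if (!nrow(df)) stop("biome polygon fixture is degenerate")
  ids <- sort(unique(df$biome_id))
  polys <- lapply(ids, function(i) {
    sub <- df[df$biome_id == i, ]
    if (nrow(sub) < 3) stop("degenerate polygon for biome ", i)
    as.matrix(sub[c("temp_c", "precip_cm")])
  })
  names(polys) <- vapply(ids, function(i) df$biome[match(i, df$biome_id)],
                         character(1))
  polys
}

# distance from points (n x 2) to a polygon boundary (min over edges),
# in already-standardized coordinates
.dist_to_polygon <- function(pts, poly) {
  m <- nrow(poly)
  d2 <- rep(Inf, nrow(pts))
  for (i in seq_len(m)) {
    a <- poly[i, ]
    b <- poly[if (i == m) 1L else i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t_ <- if (len2 == 0) rep(0, nrow(pts)) else {
      clamp01(((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2)
    }
    px <- a[1] + t_ * ab[1]
    py <- a[2] + t_ * ab[2]
    d2 <- pmin(d2, (pts[, 1] - px)^2 + (pts[, 2] - py)^2)
  }
  sqrt(d2)
}

#' Assign points in climate space to Whittaker biomes
#'
#' Point-in-polygon assignment in (temperature degC, precipitation cm)
#' space; a point inside several polygons (boundary overlap) takes the
#' lowest biome id, and a point outside every polygon takes the nearest
#' polygon by Euclidean distance in standardized (T, P) coordinates, so
#' every point receives exactly one label.
#'
#' @param temp_c mean annual temperature, degC.
#' @param precip_cm annual precipitation, cm.
#' @param polygons polygon list as from [whittaker_polygons()].
#' @return integer vector of biome ids (1-9), named by biome via the
#'   `"biomes"` attribute.
#' @export
assign_biome <- function(temp_c, precip_cm, polygons = whittaker_polygons()) {
  stopifnot(length(temp_c) == length(precip_cm))
  pts <- cbind(temp_c, precip_cm)
  lab <- rep(NA_integer_, nrow(pts))
  for (i in seq_along(polygons)) {
    hit <- is.na(lab) &
      as.logical(mgcv::in.out(rbind(polygons[[i]], polygons[[i]][1, ]), pts))
    lab[hit] <- i
  }
  out <- which(is.na(lab))
  if (length(out)) {
    all_v <- do.call(rbind, polygons)
    s_t <- stats::sd(all_v[, 1])
    s_p <- stats::sd(all_v[, 2])
    std <- cbind(pts[out, 1] / s_t, pts[out, 2] / s_p)
    dists <- vapply(polygons, function(p) {
      .dist_to_polygon(std, cbind(p[, 1] / s_t, p[, 2] / s_p))
    }, numeric(length(out)))
    if (length(out) == 1) dim(dists) <- c(1L, length(polygons))
    lab[out] <- apply(dists, 1, which.min) # ties: lowest biome id
  }
  structure(lab, biomes = names(polygons))
}

#' Biome assignment raster for a landscape
#'
#' Labels every land cell from the landscape's current-climate
#' `temp_mean` (degC) and `precip_annual` (mm, converted to cm) layers.
#' Assignment is deterministic and scenario-independent: biomes are fixed
#' at their current location.
#'
#' @param landscape the current-scenario [landscape].
#' @param polygons polygon list.
#' @return integer matrix of biome ids (`NA` off land) with a `"biomes"`
#'   attribute.
#' @export
biome_raster <- function(landscape, polygons = whittaker_polygons()) {
  cells <- land_cells(landscape)
  lab <- assign_biome(landscape$layers$temp_mean[cells],
                      landscape$layers$precip_annual[cells] / 10,
                      polygons)
  out <- matrix(NA_integer_, landscape$nrows, landscape$ncols)
  out[cells] <- lab
  attr(out, "biomes") <- attr(lab, "biomes")
  out
}

#' Richness-weighted kernel density in climate space
#'
#' Weighted centroid and 95% kernel-density contour of land cells placed in
#' (temperature degC, precipitation cm) space and weighted by their
#' richness: the "where in climate space does predicted invasion risk sit"
#' summary whose centroid shift across scenarios is interpreted. The
#' density is a weighted 2-D Gaussian kernel estimate with
#' normal-reference (plug-in) bandwidths per axis evaluated on a 256 x 256
#' grid; the contour is the density level enclosing 95% of total kernel
#' mass (by quadrature on that grid).
#'
#' @param temp_c,precip_cm coordinates of >= 10 weighted points.
#' @param weights non-negative weights, not all zero (richness).
#' @param grid_n evaluation grid side (default 256).
#' @param level kernel mass to enclose (default 0.95).
#' @return list: `centroid` (named c(temp_c, precip_cm)), `level_density`,
#'   `contours` ([grDevices::contourLines()] output), `grid` (x, y, z,
#'   cell mass `dx * dy`), `mass_inside`.
#' @export
richness_density <- function(temp_c, precip_cm, weights, grid_n = 256,
                             level = 0.95) {
  stopifnot(length(temp_c) == length(precip_cm),
            length(weights) == length(temp_c))
  if (length(temp_c) < 10) stop("need >= 10 weighted points")
  if (any(weights < 0)) stop("weights must be non-negative")
  W <- sum(weights)
  if (W == 0) stop("all weights are zero")
  w <- weights / W
  centroid <- c(temp_c = sum(w * temp_c), precip_cm = sum(w * precip_cm))

  n_eff <- 1 / sum(w^2)
  wsd <- function(x) {
    mu <- sum(w * x)
    sqrt(sum(w * (x - mu)^2) * n_eff / max(1, n_eff - 1))
  }
  # normal-reference plug-in rule per axis (2-D Gaussian product kernel)
  h <- c(wsd(temp_c), wsd(precip_cm)) * n_eff^(-1 / 6)
  h[h == 0] <- 1e-6

  gx <- seq(min(temp_c) - 3 * h[1], max(temp_c) + 3 * h[1], length.out = grid_n)
  gy <- seq(min(precip_cm) - 3 * h[2], max(precip_cm) + 3 * h[2],
            length.out = grid_n)
  Gx <- outer(gx, temp_c, function(g, x) stats::dnorm(g, x, h[1]))
  Gy <- outer(gy, precip_cm, function(g, x) stats::dnorm(g, x, h[2]))
  z <- Gx %*% (t(Gy) * w) # grid_n x grid_n density surface

  dx <- gx[2] - gx[1]
  dy <- gy[2] - gy[1]
  mass <- z * dx * dy
  total <- sum(mass)
  ord <- order(z, decreasing = TRUE)
  cum <- cumsum(mass[ord]) / total
  lvl <- z[ord][which(cum >= level)[1]]
  structure(
    list(centroid = centroid, level_density = lvl,
         contours = grDevices::contourLines(gx, gy, z, levels = lvl),
         grid = list(x = gx, y = gy, z = z, cell_mass = dx * dy),
         mass_inside = sum(mass[z >= lvl]) / total),
    class = "richness_density"
  )
}

#' Mean richness per biome
#'
#' Arithmetic mean of cell richness within each biome plus a global mean
#' over all land cells; biomes with no cells are absent from the table.
#'
#' @param richness richness matrix (`NA` off land).
#' @param assignment biome id matrix from [biome_raster()].
#' @return data.frame with `biome_id`, `biome`, `n_cells`, `mean_richness`;
#'   the global mean is the row with `biome_id = 0` (`"global"`).
#' @export
biome_means <- function(richness, assignment) {
  land <- !is.na(assignment)
  stopifnot(all(!is.na(richness[land])))
  biomes <- attr(assignment, "biomes")
  ids <- sort(unique(assignment[land]))
  per <- data.frame(
    biome_id = ids,
    biome = if (is.null(biomes)) as.character(ids) else biomes[ids],
    n_cells = vapply(ids, function(i) sum(assignment[land] == i), integer(1)),
    mean_richness = vapply(ids, function(i) {
      mean(richness[land][assignment[land] == i])
    }, numeric(1))
  )
  rbind(
    data.frame(biome_id = 0L, biome = "global", n_cells = sum(land),
               mean_richness = mean(richness[land])),
    per
  )
}
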