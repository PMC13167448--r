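#' @title Synthetic gridded landscapes
#'
#' @description
#' A `landscape` is a multi-layer gridded environment on a rectangular
#' row/column grid with a land mask, continent labels and a scenario tag.
#' The nine layers are analogues of the bioclim/land-use/soil predictors
#' commonly used in plant distribution modelling:
#' `temp_mean` (annual mean temperature, degC), `temp_range` (annual range),
#' `temp_seasonality`, `temp_warmq` (warmest-quarter mean), `precip_annual`
#' (mm), `precip_seasonality`, `precip_warmq` (mm),
#' `landuse_natural_fraction` (share of primary/secondary vegetation, 0-1)
#' and `soil_ph`.
#'
#' Grids are unit-cell, row-major displayed, `[row, col]` indexed (no
#' geographic CRS in synthetic mode); linear cell indices are column-major
#' as returned by [which()] on the land mask.
#' @name landscape
NULL

LAYER_NAMES <- c(
  "temp_mean", "temp_range", "temp_seasonality", "temp_warmq",
  "precip_annual", "precip_seasonality", "precip_warmq",
  "landuse_natural_fraction", "soil_ph"
)

SCENARIO_TAGS <- c("current", "mild_r1", "mild_r2", "severe_r1", "severe_r2")

#' The two alternative predictor sets
#'
#' Two parallel predictor sets are carried through the whole pipeline; models
#' built from different sets are never mixed within one ensemble. Set 1
#' pairs annual means with annual variability; set 2 uses seasonality and
#' warmest-quarter variables. Both share the land-use and soil-pH layers.
#'
#' @return named list of character vectors of layer names.
#' @export
predictor_sets <- function() {
  list(
    set1 = c("temp_mean", "temp_range", "precip_annual",
             "precip_seasonality", "landuse_natural_fraction", "soil_ph"),
    set2 = c("temp_seasonality", "temp_warmq", "precip_seasonality",
             "precip_warmq", "landuse_natural_fraction", "soil_ph")
  )
}

#' Climatic variables of a predictor set
#'
#' The climatic subset of a predictor set (land use and soil pH excluded);
#' used by the environmental-space occurrence filter and the surface range
#' envelope, both of which are climatic-range concepts.
#'
#' @param set predictor-set id (`"set1"` or `"set2"`) or a character vector
#'   of layer names.
#' @return character vector of climatic layer names.
#' @export
climatic_vars <- function(set) {
  vars <- if (length(set) == 1 && set %in% names(predictor_sets())) {
    predictor_sets()[[set]]
  } else {
    set
  }
  setdiff(vars, c("landuse_natural_fraction", "soil_ph"))
}

new_landscape <- function(nrows, ncols, layers, land, continent, scenario, seed) {
  # pmax/pmin with scalar first arguments drop dim attributes; normalize
  layers <- lapply(layers, function(m) matrix(as.numeric(m), nrows, ncols))
  structure(
    list(nrows = nrows, ncols = ncols, layers = layers, land = land,
         continent = continent, scenario = scenario, seed = seed),
    class = "landscape"
  )
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf(
    "<landscape %dx%d, scenario '%s', %d land cells, %d continents>\n",
    x$nrows, x$ncols, x$scenario, sum(x$land),
    length(unique(x$continent[x$land]))
  ))
  invisible(x)
}

#' Linear indices of land cells
#' @param ls a `landscape`.
#' @return integer vector of column-major cell indices.
#' @export
land_cells <- function(ls) which(ls$land)

#' Convert linear cell indices to (row, col)
#' @param ls a `landscape`.
#' @param cells integer linear indices.
#' @return data.frame with columns `row`, `col`.
#' @export
cell_rowcol <- function(ls, cells) {
  data.frame(
    row = ((cells - 1L) %% ls$nrows) + 1L,
    col = ((cells - 1L) %/% ls$nrows) + 1L
  )
}

#' Convert (row, col) to linear cell indices
#' @param ls a `landscape`.
#' @param row,col integer vectors.
#' @return integer linear indices.
#' @export
cell_index <- function(ls, row, col) {
  (as.integer(col) - 1L) * ls$nrows + as.integer(row)
}

#' Extract layer values at cells
#' @param ls a `landscape`.
#' @param layers character vector of layer names.
#' @param cells linear cell indices; defaults to all land cells.
#' @return data.frame, one column per layer.
#' @export
cell_env <- function(ls, layers, cells = land_cells(ls)) {
  bad <- setdiff(layers, names(ls$layers))
  if (length(bad)) {
    stop("unknown landscape layer(s): ", paste(bad, collapse = ", "))
  }
  out <- lapply(ls$layers[layers], function(m) m[cells])
  as.data.frame(out)
}

# --- smooth random fields ---------------------------------------------------

# separable Gaussian blur; zero padding with truncated-kernel
# renormalisation keeps the field variance near-stationary at the borders
gaussian_smooth <- function(m, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  conv_rows <- function(mm) {
    n <- nrow(mm)
    pad <- matrix(0, r, ncol(mm))
    padded <- rbind(pad, mm, pad)
    out <- matrix(0, n, ncol(mm))
    for (j in seq_along(k)) {
      out <- out + k[j] * padded[j:(j + n - 1L), , drop = FALSE]
    }
    out
  }
  blur <- function(mm) t(conv_rows(t(conv_rows(mm))))
  blur(m) / blur(matrix(1, nrow(m), ncol(m)))
}

# standardized smooth Gaussian random field (mean 0, sd 1)
smooth_noise <- function(nr, nc, sigma) {
  f <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
  (f - mean(f)) / stats::sd(f)
}

# 4-connected component labelling of a logical mask (flood fill)
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(NA_integer_, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (!is.na(lab[start])) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      cell <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      r <- ((cell - 1L) %% nr) + 1L
      c <- ((cell - 1L) %/% nr) + 1L
      for (d in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
        if (d[1] >= 1L && d[1] <= nr && d[2] >= 1L && d[2] <= nc) {
          nb <- (d[2] - 1L) * nr + d[1]
          if (mask[nb] && is.na(lab[nb])) {
            lab[nb] <- cur
            queue <- c(queue, nb)
          }
        }
      }
    }
  }
  lab
}

# --- world generation -------------------------------------------------------

#' Default scenario parameters for the synthetic futures
#'
#' Additive warming and precipitation/land-use multipliers for a mild
#' (sustainability-like, SSP1 analogue) and a severe (fossil-fuelled, SSP5
#' analogue) end-of-century scenario, plus the amplitude of the smooth
#' realization noise that plays the role of between-GCM spread. Each scenario
#' is realized twice (`r1`, `r2`) with independent noise fields.
#'
#' @return named list of scenario parameters.
#' @export
default_scenario_params <- function() {
  list(
    delta_mild = 1.8,        # degC added to temperature means, mild scenario
    delta_severe = 3.7,      # degC, severe scenario
    precip_mult_mild = 1.03, # multiplicative precipitation change
    precip_mult_severe = 0.92,
    landuse_loss_mild = 0.05,   # mean loss of natural-vegetation fraction
    landuse_loss_severe = 0.15,
    noise_sd = 0.4,          # degC sd of the smooth realization (GCM) noise
    realization_seeds = c(r1 = 1L, r2 = 2L)
  )
}

# internal: correlations within each predictor set must stay |r| <= 0.70
.sets_collinear <- function(layers, land, max_abs_r = 0.70) {
  for (set in predictor_sets()) {
    vals <- vapply(layers[set], function(m) m[land], numeric(sum(land)))
    r <- stats::cor(vals)
    diag(r) <- 0
    if (any(abs(r) > max_abs_r)) return(TRUE)
  }
  FALSE
}

.base_layers <- function(nr, nc, sigma) {
  lat <- matrix(rep((seq_len(nr) - 1) / (nr - 1), nc), nr, nc)
  lon <- matrix(rep((seq_len(nc) - 1) / (nc - 1), each = nr), nr, nc)
  n <- replicate(9, smooth_noise(nr, nc, sigma), simplify = FALSE)
  # equator at mid-grid, poles at the top and bottom rows: every 2x2
  # spatial block then spans the full tropical-to-polar gradient, as the
  # quadrants of a global calibration area do
  fold <- abs(2 * lat - 1)
  lonfold <- abs(2 * lon - 1) # east-west "continentality" proxy
  list(
    temp_mean = 30 - 45 * fold + 4 * n[[1]],
    temp_range = 12 + 12 * lonfold + 5 * n[[2]],
    temp_seasonality = 2 + 6 * fold + 3 * n[[3]],
    temp_warmq = 35 - 45 * fold + 3.5 * n[[4]],
    precip_annual = pmax(10, 500 + 1300 * exp(-(fold / 0.45)^2) +
                           600 * n[[5]]),
    precip_seasonality = 40 + 25 * stats::plogis(1.5 * n[[6]]),
    precip_warmq = NA, # filled below from precip_annual
    landuse_natural_fraction = stats::plogis(0.6 + 1.3 * n[[8]]),
    soil_ph = pmin(9, pmax(3.5, 6.3 + 0.8 * n[[9]])),
    .n7 = n[[7]]
  )
}

#' Generate a synthetic world: one landscape per scenario tag
#'
#' Builds a `current` landscape plus four futures (`mild`/`severe` scenario
#' times two realization seeds `r1`/`r2`). All five share the land mask,
#' continent labels and the soil-pH layer; futures shift the temperature
#' layers by the scenario's warming plus spatially smooth realization noise,
#' rescale precipitation, and reduce the natural land-use fraction. Layer
#' noise is regenerated until no pair of layers within either predictor set
#' has |Pearson r| > 0.70 over land.
#'
#' @param seed integer master seed.
#' @param shape integer c(nrows, ncols), each at least 20.
#' @param scenario_params list as produced by [default_scenario_params()].
#' @return an object of class `world`: named list of five [landscape]s
#'   (`current`, `mild_r1`, `mild_r2`, `severe_r1`, `severe_r2`).
#' @export
make_world <- function(seed, shape = c(60, 60),
                       scenario_params = default_scenario_params()) {
  if (length(shape) != 2 || any(shape < 20)) {
    stop("shape must be at least 20 x 20")
  }
  sp <- scenario_params
  if (sp$delta_mild >= sp$delta_severe) {
    stop("scenario_params: delta_mild must be smaller than delta_severe")
  }
  nr <- as.integer(shape[1])
  nc <- as.integer(shape[2])
  sigma <- max(2, min(nr, nc) / 12)

  # land mask + continents: threshold a smooth blob field, then carve a
  # meandering ocean channel so the land always splits into >= 2 sizeable
  # connected components; retry on degenerate draws
  land <- continent <- NULL
  for (attempt in 1:50) {
    mask <- with_seed(derive_seed(seed, "land", attempt), {
      f <- smooth_noise(nr, nc, max(3, min(nr, nc) / 8))
      m <- f > stats::quantile(f, 0.40)
      phase <- stats::runif(1, 0, 2 * pi)
      width <- max(1, round(0.04 * nc))
      centre <- nc / 2 + 0.22 * nc * sin(2 * pi * seq_len(nr) / nr + phase)
      for (r in seq_len(nr)) {
        lo <- max(1L, floor(centre[r] - width))
        hi <- min(nc, ceiling(centre[r] + width))
        m[r, lo:hi] <- FALSE
      }
      m
    })
    lab <- label_components(mask)
    sizes <- table(lab[!is.na(lab)])
    big <- as.integer(names(sizes)[sizes >= 10])
    if (length(big) >= 2) {
      mask[!is.na(lab) & !(lab %in% big)] <- FALSE
      lab[!(lab %in% big)] <- NA_integer_
      lab[!mask] <- NA_integer_
      land <- mask
      continent <- matrix(match(lab, big), nr, nc)
      break
    }
  }
  if (is.null(land)) stop("could not generate a land mask with >= 2 continents")

  # current layers, regenerated until the collinearity screen is satisfied
  layers <- NULL
  for (attempt in 1:30) {
    cand <- with_seed(derive_seed(seed, "layers", attempt), {
      b <- .base_layers(nr, nc, sigma)
      b$precip_warmq <- pmax(0, 0.35 * b$precip_annual + 150 * b$.n7)
      b$.n7 <- NULL
      b
    })
    if (!.sets_collinear(cand, land)) {
      layers <- cand
      break
    }
  }
  if (is.null(layers)) stop("could not generate layers with |r| <= 0.70")
  layers <- layers[LAYER_NAMES]

  current <- new_landscape(nr, nc, layers, land, continent, "current", seed)
  world <- list(current = current)

  for (scen in c("mild", "severe")) {
    delta <- if (scen == "mild") sp$delta_mild else sp$delta_severe
    pmult <- if (scen == "mild") sp$precip_mult_mild else sp$precip_mult_severe
    loss <- if (scen == "mild") sp$landuse_loss_mild else sp$landuse_loss_severe
    for (rname in names(sp$realization_seeds)) {
      rseed <- sp$realization_seeds[[rname]]
      fut <- NULL
      for (attempt in 1:30) {
        cand <- with_seed(derive_seed(seed, "future", scen, rseed, attempt), {
          nz <- replicate(6, smooth_noise(nr, nc, sigma), simplify = FALSE)
          ly <- layers
          ly$temp_mean <- ly$temp_mean + delta + sp$noise_sd * nz[[1]]
          ly$temp_warmq <- ly$temp_warmq + delta + sp$noise_sd * nz[[2]]
          ly$temp_range <- ly$temp_range + 0.25 * delta +
            0.5 * sp$noise_sd * nz[[3]]
          ly$temp_seasonality <- pmax(
            0.5, ly$temp_seasonality + 0.25 * delta +
              0.5 * sp$noise_sd * nz[[3]]
          )
          ly$precip_annual <- pmax(
            5, ly$precip_annual * pmult * exp(0.05 * nz[[4]])
          )
          ly$precip_warmq <- pmax(
            0, ly$precip_warmq * pmult * exp(0.05 * nz[[5]])
          )
          ly$landuse_natural_fraction <- clamp01(
            ly$landuse_natural_fraction -
              loss * (0.5 + stats::plogis(2 * nz[[6]]))
          )
          # soil pH has no future scenarios: held fixed across tags
          ly$soil_ph <- layers$soil_ph
          ly
        })
        if (!.sets_collinear(cand, land)) {
          fut <- cand
          break
        }
      }
      if (is.null(fut)) stop("could not generate future layers with |r| <= 0.70")
      tag <- paste0(scen, "_", rname)
      world[[tag]] <- new_landscape(nr, nc, fut, land, continent, tag, seed)
    }
  }
  structure(world, class = "world")
}

#' @export
print.world <- function(x, ...) {
  cat(sprintf("<world: %s>\n", paste(names(x), collapse = ", ")))
  print(x$current)
  invisible(x)
}
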