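#' Collinearity screen over land cells
#'
#' Pairwise Pearson correlations of a set of layers over land; the screen
#' fails if any pair strictly exceeds `|r| = 0.70` (a pair at exactly 0.70
#' passes), or if any layer is constant (correlation undefined).
#'
#' @param landscape a [landscape].
#' @param layers character vector of >= 2 layer names.
#' @param max_abs_r threshold (default 0.70).
#' @return list with `pass` (logical), `pairs` (data.frame `var1`, `var2`,
#'   `r` for every pair), `offending` (subset with `|r| > max_abs_r`), and
#'   `reason` (character, non-empty on constant layers).
#' @export
collinearity_screen <- function(landscape, layers, max_abs_r = 0.70) {
  if (length(layers) < 2) stop("need >= 2 layers")
  vals <- cell_env(landscape, layers)
  const <- names(vals)[vapply(vals, function(x) stats::sd(x) == 0, logical(1))]
  if (length(const)) {
    return(list(pass = FALSE, pairs = NULL, offending = NULL,
                reason = paste("constant layer(s), correlation undefined:",
                               paste(const, collapse = ", "))))
  }
  r <- stats::cor(as.matrix(vals))
  ut <- which(upper.tri(r), arr.ind = TRUE)
  pairs <- data.frame(var1 = layers[ut[, 1]], var2 = layers[ut[, 2]],
                      r = r[ut])
  offending <- pairs[abs(pairs$r) > max_abs_r, , drop = FALSE]
  list(pass = nrow(offending) == 0, pairs = pairs, offending = offending,
       reason = "")
}

#' Assign calibration points to four spatial blocks
#'
#' 2x2 quadrants split at the median row and median column of the
#' calibration points (presences plus pseudo-absences). Points lying exactly
#' on a median go to the lower-index block. Used to build spatially
#' separated cross-validation folds.
#'
#' @param points data.frame with `row` and `col`.
#' @return object of class `block_partition`: integer vector of block ids
#'   (1-4, one per point) with the split medians as attributes.
#' @export
make_blocks <- function(points) {
  stopifnot(all(c("row", "col") %in% names(points)))
  if (nrow(points) < 4) stop("need >= 4 points")
  mr <- stats::median(points$row)
  mc <- stats::median(points$col)
  block <- 1L + 2L * (points$row > mr) + (points$col > mc)
  if (length(unique(block)) < 4) {
    stop("a spatial block is empty; more (or better spread) data are needed")
  }
  structure(as.integer(block), class = "block_partition",
            median_row = mr, median_col = mc)
}

# ---- the four model families ----------------------------------------------

ALGORITHMS <- c("glm", "gam", "rf", "brt")

# build the model frame used by all algorithms
.sdm_frame <- function(presences, pas, predictor_set) {
  stopifnot(inherits(presences, "occurrence_set"))
  pres <- presences$records[predictor_set]
  abs_ <- pas$records[predictor_set]
  df <- rbind(pres, abs_)
  df$.y <- rep(c(1, 0), c(nrow(pres), nrow(abs_)))
  df
}

#' Fit one species distribution model
#'
#' Regresses the binary presence/pseudo-absence response on the predictor
#' set with one of four families, each at the conventional defaults of
#' ensemble SDM practice:
#' \describe{
#'   \item{`glm`}{logistic regression over linear and quadratic terms per
#'     predictor (second-order formula, able to express unimodal
#'     responses), with stepwise AIC term selection starting from the full
#'     model — the selection step keeps uninformative predictors from
#'     steering out-of-block extrapolation;}
#'   \item{`gam`}{binomial additive model with shrinkage thin-plate
#'     smooths (`mgcv`, `bs = "ts"`, basis dimension 5, REML smoothness
#'     selection);}
#'   \item{`rf`}{random forest classifier, 500 trees (`randomForest`
#'     defaults);}
#'   \item{`brt`}{boosted regression trees, logistic loss, with the
#'     slow-learning settings recommended for distribution modelling:
#'     150 rounds, learning rate 0.05, interaction depth 2, bag fraction
#'     0.75 (`xgboost`, single thread).}
#' }
#' The stochastic tree methods are seeded, so a fit is a pure function of
#' its inputs; predictions are clamped to `[0, 1]`.
#'
#' @param algorithm one of `"glm"`, `"gam"`, `"rf"`, `"brt"`.
#' @param presences an [occurrence_set] (stage `"env_filtered"` in the
#'   pipeline).
#' @param pas a `pa_set` with as many records as there are presences.
#' @param predictor_set character vector of predictor layer names.
#' @param seed integer seed.
#' @return object of class `fitted_sdm` with elements `algorithm`,
#'   `predictor_set`, `model`, `seed`, `cv_boyce` (NA until cross-validated).
#' @export
fit_sdm <- function(algorithm, presences, pas, predictor_set, seed = 1) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  df <- .sdm_frame(presences, pas, predictor_set)
  const <- predictor_set[vapply(df[predictor_set],
                                function(x) stats::sd(x) == 0, logical(1))]
  if (length(const)) {
    stop("constant predictor(s) make the design singular: ",
         paste(const, collapse = ", "))
  }
  model <- with_seed(seed, {
    switch(algorithm,
      glm = {
        terms <- paste(
          vapply(predictor_set, function(v) {
            sprintf("%s + I(%s^2)", v, v)
          }, character(1)),
          collapse = " + "
        )
        full <- stats::glm(stats::as.formula(paste(".y ~", terms)),
                           data = df, family = stats::binomial())
        suppressWarnings(stats::step(full, direction = "both", trace = 0))
      },
      gam = {
        terms <- paste(vapply(predictor_set, function(v) {
          k <- min(5L, length(unique(df[[v]])) - 1L)
          if (k >= 3) sprintf('s(%s, k = %d, bs = "ts")', v, k) else v
        }, character(1)), collapse = " + ")
        mgcv::gam(stats::as.formula(paste(".y ~", terms)), data = df,
                  family = stats::binomial(), method = "REML")
      },
      rf = randomForest::randomForest(
        x = df[predictor_set], y = factor(df$.y, levels = c(0, 1)),
        ntree = 500
      ),
      brt = xgboost::xgboost(
        x = as.matrix(df[predictor_set]),
        y = factor(df$.y, levels = c(0, 1)),
        nrounds = 150, max_depth = 2, learning_rate = 0.05,
        subsample = 0.75, nthreads = 1, seed = seed, verbosity = 0
      )
    )
  })
  structure(
    list(algorithm = algorithm, predictor_set = predictor_set, model = model,
         seed = seed, cv_boyce = NA_real_),
    class = "fitted_sdm"
  )
}

#' Predict suitability from a fitted SDM
#'
#' @param object a `fitted_sdm`.
#' @param newdata data.frame containing the predictor columns.
#' @param ... unused.
#' @return numeric vector of suitabilities in `[0, 1]`.
#' @export
predict.fitted_sdm <- function(object, newdata, ...) {
  p <- switch(object$algorithm,
    glm = stats::predict(object$model, newdata = newdata, type = "response"),
    gam = as.numeric(stats::predict(object$model, newdata = newdata,
                                    type = "response")),
    rf = predict(object$model, newdata = newdata[object$predictor_set],
                 type = "prob")[, "1"],
    brt = predict(object$model, as.matrix(newdata[object$predictor_set]))
  )
  clamp01(as.numeric(p))
}

#' Predict suitability over a landscape
#'
#' @param model a `fitted_sdm` (or any object with a `predict` method over
#'   an environment data.frame).
#' @param landscape a [landscape].
#' @return suitability matrix (`NA` off land).
#' @export
predict_raster <- function(model, landscape) {
  cells <- land_cells(landscape)
  env <- cell_env(landscape, model$predictor_set, cells)
  out <- matrix(NA_real_, landscape$nrows, landscape$ncols)
  out[cells] <- predict(model, env)
  out
}

#' Spatial block cross-validation with the continuous Boyce index
#'
#' Four folds from a [make_blocks()] partition of the calibration points:
#' each fold trains the algorithm on three blocks and scores the held-out
#' block's presences with the Boyce index. The default background
#' (`background = "calibration"`) is the held-out block's own calibration
#' points (presences plus pseudo-absences), the convention of ensemble-SDM
#' validation: because the scored presences are part of the background, the
#' P/E ratio is bounded and its upper plateau stable even when predictions
#' saturate. `background = "landscape"` instead uses predictions at every
#' land cell (availability in the strict sense); it is unbiased but far
#' noisier at small presence counts, since windows with near-zero expected
#' frequency produce wild P/E excursions. Folds whose Boyce index is
#' undefined, or with no held-out presences, are dropped with a warning;
#' the cross-validated score is the mean over the remaining folds, or `NA`
#' if all four are dropped (the model is then rejected). Folds holding out
#' fewer than `min_fold_presences` presences are likewise dropped: a P/E
#' curve built from a handful of presences is noise, not evaluation (the
#' same reasoning behind the index's own minimum background size).
#'
#' @param algorithm model family id (see [fit_sdm()]).
#' @param presences an [occurrence_set].
#' @param pas a `pa_set`.
#' @param predictor_set character vector of predictor layer names.
#' @param blocks a `block_partition` over `rbind(presences, pas)` points (in
#'   that order).
#' @param landscape the calibration [landscape] (supplies the background
#'   when `background = "landscape"`).
#' @param seed integer seed.
#' @param boyce_window,boyce_n_windows Boyce parameters (see
#'   [boyce_index()]).
#' @param background `"calibration"` (held-out presences + pseudo-absences,
#'   default) or `"landscape"` (all land cells).
#' @param min_fold_presences minimum held-out presences for a fold to be
#'   scored (default 10).
#' @return list: `cv_boyce` (mean over defined folds, `NA` if none),
#'   `fold_boyce` (length 4, `NA` for dropped folds).
#' @export
cross_validate <- function(algorithm, presences, pas, predictor_set, blocks,
                           landscape, seed = 1, boyce_window = 0.1,
                           boyce_n_windows = 101,
                           background = c("calibration", "landscape"),
                           min_fold_presences = 10) {
  background <- match.arg(background)
  n_pres <- nrow(presences$records)
  n_pa <- nrow(pas$records)
  stopifnot(length(blocks) == n_pres + n_pa)
  pres_block <- blocks[seq_len(n_pres)]
  pa_block <- blocks[n_pres + seq_len(n_pa)]
  fold_boyce <- rep(NA_real_, 4)
  for (b in 1:4) {
    hold_pres <- pres_block == b
    if (sum(hold_pres) < min_fold_presences) {
      warning(sprintf("fold %d holds out %d presence(s) (< %d); fold dropped",
                      b, sum(hold_pres), min_fold_presences))
      next
    }
    tr_pres <- occurrence_set(
      presences$records[!hold_pres, , drop = FALSE],
      presences$species_id, presences$stage
    )
    tr_pa <- list(records = pas$records[pa_block != b, , drop = FALSE])
    fb <- tryCatch({
      m <- fit_sdm(algorithm, tr_pres, tr_pa, predictor_set,
                   seed = derive_seed(seed, "cv", algorithm, b))
      pp <- predict(
        m, presences$records[hold_pres, predictor_set, drop = FALSE]
      )
      bg <- if (background == "landscape") {
        predict(m, cell_env(landscape, predictor_set))
      } else {
        c(pp, predict(m, pas$records[pa_block == b, predictor_set,
                                     drop = FALSE]))
      }
      boyce_index(pp, bg, window_width = boyce_window,
                  n_windows = boyce_n_windows)$index
    },
    boyce_undefined = function(e) {
      warning(sprintf("fold %d: %s; fold dropped", b, conditionMessage(e)))
      NA_real_
    },
    error = function(e) {
      warning(sprintf("fold %d failed (%s); fold dropped", b,
                      conditionMessage(e)))
      NA_real_
    })
    fold_boyce[b] <- fb
  }
  cv <- if (all(is.na(fold_boyce))) NA_real_ else mean(fold_boyce, na.rm = TRUE)
  list(cv_boyce = cv, fold_boyce = fold_boyce)
}

#' Fit and cross-validate one algorithm for one species
#'
#' Runs [cross_validate()] for the weight-giving score, then refits the
#' algorithm on all calibration data; the returned model carries its
#' cross-validated Boyce score and is the one used for projection.
#'
#' @inheritParams cross_validate
#' @return a `fitted_sdm` with `cv_boyce` and `fold_boyce` filled in, or
#'   `NULL` if the full-data fit fails.
#' @export
fit_cv_sdm <- function(algorithm, presences, pas, predictor_set, blocks,
                       landscape, seed = 1, boyce_window = 0.1,
                       boyce_n_windows = 101,
                       background = c("calibration", "landscape"),
                       min_fold_presences = 10) {
  cv <- cross_validate(algorithm, presences, pas, predictor_set, blocks,
                       landscape, seed = seed, boyce_window = boyce_window,
                       boyce_n_windows = boyce_n_windows,
                       background = background,
                       min_fold_presences = min_fold_presences)
  m <- tryCatch(
    fit_sdm(algorithm, presences, pas, predictor_set,
            seed = derive_seed(seed, "refit", algorithm)),
    error = function(e) NULL
  )
  if (is.null(m)) return(NULL)
  m$cv_boyce <- cv$cv_boyce
  m$fold_boyce <- cv$fold_boyce
  m
}
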