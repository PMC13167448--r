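#' Build a Boyce-weighted ensemble from cross-validated models
#'
#' Retains only models whose cross-validated Boyce index is strictly
#' greater than the retention threshold (default 0.6, "good model
#' performance"); the retained members are combined by a weighted average
#' with weights proportional to their Boyce scores. A species whose models
#' are all rejected is flagged unmodellable and excluded downstream.
#' Members of one ensemble always share a predictor set.
#'
#' @param models list of `fitted_sdm` objects with `cv_boyce` filled in.
#' @param retention retention threshold on `cv_boyce` (strict; default 0.6).
#' @return object of class `ensemble_model`: `members`, `weights`
#'   (proportional to `cv_boyce`, summing to 1), `retention`, `retained`
#'   (logical), `threshold` (`t*`, NA until [boyce_max_threshold()] is
#'   applied), `projections` (empty registry).
#' @export
build_ensemble <- function(models, retention = 0.6) {
  if (!length(models)) stop("need >= 1 model")
  models <- Filter(Negate(is.null), models)
  cv <- vapply(models, function(m) m$cv_boyce, numeric(1))
  keep <- !is.na(cv) & cv > retention
  members <- models[keep]
  weights <- if (any(keep)) cv[keep] / sum(cv[keep]) else numeric(0)
  structure(
    list(members = members, weights = weights, retention = retention,
         retained = any(keep), threshold = NA_real_,
         predictor_set = if (any(keep)) members[[1]]$predictor_set else NULL,
         projections = list()),
    class = "ensemble_model"
  )
}

#' @export
print.ensemble_model <- function(x, ...) {
  if (!x$retained) {
    cat("<ensemble_model: unmodellable (no member with cv_boyce >",
        x$retention, ")>\n")
  } else {
    cat(sprintf(
      "<ensemble_model: %d member(s) [%s], t* = %s>\n", length(x$members),
      paste(vapply(x$members, `[[`, character(1), "algorithm"),
            collapse = ", "),
      ifelse(is.na(x$threshold), "unset", format(x$threshold))
    ))
  }
  invisible(x)
}

#' Ensemble suitability prediction over an environment table
#'
#' @param object an `ensemble_model` with at least one member.
#' @param newdata data.frame of predictor columns.
#' @param ... unused.
#' @return weighted-mean suitability vector in `[0, 1]`.
#' @export
predict.ensemble_model <- function(object, newdata, ...) {
  if (!object$retained) stop("ensemble has no retained members")
  preds <- vapply(object$members, function(m) predict(m, newdata),
                  numeric(nrow(newdata)))
  if (nrow(newdata) == 1) dim(preds) <- c(1L, length(object$members))
  as.numeric(preds %*% object$weights)
}

#' Project an ensemble over a landscape and register the raster
#'
#' Cellwise Boyce-weighted mean of the member predictions, registered in the
#' ensemble's projection registry under the landscape's scenario tag.
#'
#' @param ensemble an `ensemble_model`.
#' @param landscape a [landscape] whose layers cover the predictor set.
#' @return the updated `ensemble_model`; the raster is
#'   `ensemble$projections[[scenario_tag]]`.
#' @export
predict_ensemble <- function(ensemble, landscape) {
  if (!ensemble$retained) stop("ensemble has no retained members")
  missing_layers <- setdiff(ensemble$predictor_set, names(landscape$layers))
  if (length(missing_layers)) {
    stop("landscape lacks layer(s): ", paste(missing_layers, collapse = ", "))
  }
  cells <- land_cells(landscape)
  suit <- matrix(NA_real_, landscape$nrows, landscape$ncols)
  suit[cells] <- predict(ensemble,
                         cell_env(landscape, ensemble$predictor_set, cells))
  ensemble$projections[[landscape$scenario]] <- suit
  ensemble
}

#' Boyce-maximization binarization threshold
#'
#' Derives the suitability cut-off `t*` from the Boyce P/E curve of the
#' current-scenario ensemble prediction: the lowest retained window midpoint
#' from which the predicted-to-expected ratio stays at or above 1 for every
#' retained midpoint upwards (the stable `P/E >= 1` crossing). Above `t*`
#' presences are over-represented relative to availability, so cells there
#' are classified suitable. If `F >= 1` everywhere the lowest midpoint is
#' returned; if the curve never stabilizes above 1 the species cannot be
#' binarized and `NA` is returned (species flagged and excluded).
#'
#' `method = "fmax"` instead returns the midpoint with the maximal `F`
#' (lowest such midpoint on ties), a simpler grid alternative.
#'
#' @param suitability_at_presences ensemble suitability at presence cells.
#' @param suitability_background ensemble suitability at all land cells.
#' @param window_width,n_windows Boyce curve parameters.
#' @param method `"crossing"` (default) or `"fmax"`.
#' @return `t*` in `[0, 1]`, or `NA` if no stable crossing exists.
#' @export
boyce_max_threshold <- function(suitability_at_presences,
                                suitability_background,
                                window_width = 0.1, n_windows = 101,
                                method = c("crossing", "fmax")) {
  method <- match.arg(method)
  curve <- boyce_index(suitability_at_presences, suitability_background,
                       window_width = window_width,
                       n_windows = n_windows)$curve
  if (method == "fmax") {
    return(curve$midpoint[which.max(curve$F)])
  }
  ge1 <- curve$F >= 1
  stable <- rev(cumprod(rev(ge1))) == 1 # TRUE where F >= 1 from here upward
  if (!any(stable)) return(NA_real_)
  min(curve$midpoint[stable])
}

#' Binarize a suitability raster at a threshold
#'
#' Suitable (1) iff suitability `>= t`; the same per-species threshold is
#' applied to every scenario projection of that species and predictor set.
#'
#' @param suitability numeric matrix (`NA` off land).
#' @param threshold `t*` in `[0, 1]`.
#' @return integer 0/1 matrix (`NA` off land).
#' @export
binarize <- function(suitability, threshold) {
  if (is.na(threshold)) stop("threshold is undefined")
  out <- suitability
  out[!is.na(out)] <- as.integer(out[!is.na(out)] >= threshold)
  out
}
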