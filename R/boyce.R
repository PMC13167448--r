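#' Continuous Boyce index
#'
#' Measures how far model predictions at presences depart from a random
#' distribution of presences over the available environment. Overlapping
#' suitability windows of width `window_width` are centred on `n_windows`
#' evenly spaced midpoints covering `[0, 1]`; for each window `i`,
#' `P_i` is the share of presence predictions falling in the window, `E_i`
#' the share of background predictions, and `F_i = P_i / E_i` the
#' predicted-to-expected ratio. Windows with `E_i = 0` are dropped. The
#' index is the Spearman rank correlation between `F_i` and the window
#' midpoints: 1 for a model that ranks presences perfectly, 0 for a random
#' model, -1 for an inverted one. Being a rank statistic, it is invariant
#' to strictly increasing transformations of the predictions.
#'
#' @param pred_presence predictions at presence points, in `[0, 1]`.
#' @param pred_background predictions over the background (available
#'   environment), in `[0, 1]`; at least 10 values.
#' @param window_width suitability window width (default 0.1).
#' @param n_windows number of window midpoints (default 101).
#' @return object of class `boyce_result`: list with `index` and `curve`
#'   (data.frame `midpoint`, `P`, `E`, `F` over retained windows).
#' @export
boyce_index <- function(pred_presence, pred_background,
                        window_width = 0.1, n_windows = 101) {
  if (length(pred_presence) < 1) stop("need >= 1 presence prediction")
  if (length(pred_background) < 10) stop("need >= 10 background predictions")
  all_pred <- c(pred_presence, pred_background)
  if (any(!is.finite(all_pred)) || any(all_pred < 0 | all_pred > 1)) {
    stop("predictions must be finite and within [0, 1]")
  }
  if (length(unique(all_pred)) == 1) {
    stop(boyce_undefined("all predictions are identical; Boyce index undefined"))
  }
  w <- window_width
  mids <- seq(w / 2, 1 - w / 2, length.out = n_windows)
  P <- E <- numeric(n_windows)
  for (i in seq_len(n_windows)) {
    lo <- mids[i] - w / 2
    hi <- mids[i] + w / 2
    P[i] <- mean(pred_presence >= lo & pred_presence <= hi)
    E[i] <- mean(pred_background >= lo & pred_background <= hi)
  }
  keep <- E > 0
  if (sum(keep) < 3) {
    stop(boyce_undefined("fewer than 3 windows contain background predictions"))
  }
  FF <- P[keep] / E[keep]
  if (stats::sd(FF) == 0) {
    stop(boyce_undefined("P/E ratio is constant; Boyce index undefined"))
  }
  idx <- stats::cor(FF, mids[keep], method = "spearman")
  structure(
    list(index = idx,
         curve = data.frame(midpoint = mids[keep], P = P[keep], E = E[keep],
                            F = FF)),
    class = "boyce_result"
  )
}

# condition signalling a structurally undefined Boyce index (as opposed to a
# numerical failure); callers drop the fold / flag the species
boyce_undefined <- function(msg) {
  structure(class = c("boyce_undefined", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' @export
print.boyce_result <- function(x, ...) {
  cat(sprintf("<boyce_result: index %.3f over %d windows>\n",
              x$index, nrow(x$curve)))
  invisible(x)
}
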