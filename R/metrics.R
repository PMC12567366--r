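#' Regression quality metrics: R-squared, RMSE, RPD
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`,
#' `RMSE = sqrt(mean((y - yhat)^2))` and the residual predictive deviation
#' `RPD = SD(y) / RMSE`.  With the default population-SD convention (same
#' `n` denominator as `R^2`'s total sum of squares) the identity
#' `RPD = (1 - R^2)^(-1/2)` holds exactly; the sample-SD variant differs by
#' `sqrt(n/(n-1))` and is available via `sdType`.
#'
#' @param yTrue,yPred equal-length numeric vectors (>= 2); `yTrue` must
#'   have variance.
#' @param sdType `"population"` (default) or `"sample"` SD in the RPD.
#' @param folds optional per-fold metrics data.frame to attach.
#' @return a [RegressionMetrics-class]; `rpd` is `Inf` when `rmse` is 0.
#' @export
regressionMetrics <- function(yTrue, yPred,
                              sdType = c("population", "sample"),
                              folds = data.frame()) {
  sdType <- match.arg(sdType)
  stopIfNot(length(yTrue) == length(yPred), "length mismatch")
  n <- length(yTrue)
  stopIfNot(n >= 2L, "need at least 2 pairs")
  sst <- sum((yTrue - mean(yTrue))^2)
  stopIfNot(sst > 0, "yTrue has zero variance; R-squared is undefined")
  sse <- sum((yTrue - yPred)^2)
  rmse <- sqrt(sse / n)
  sdy <- if (sdType == "population") sqrt(sst / n) else sqrt(sst / (n - 1L))
  rpd <- if (rmse == 0) Inf else sdy / rmse
  new("RegressionMetrics", r2 = 1 - sse / sst, rmse = rmse, rpd = rpd,
      n = as.integer(n), folds = folds)
}

setMethod("show", "RegressionMetrics", function(object) {
  cat(sprintf("RegressionMetrics (n = %d): R2 = %.3f, RMSE = %.4g, RPD = %.3g\n",
              object@n, object@r2, object@rmse, object@rpd))
})

#' ROC curve and AUC by the rank method
#'
#' AUC is the Mann--Whitney statistic: the probability that a random
#' positive outscores a random negative, with half credit for ties
#' (computed from average ranks).  ROC points are emitted at every distinct
#' score cutoff (decision rule `score >= cutoff` is positive), plus the
#' (0,0) endpoint.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels positive/negative labels: logical, 0/1 or
#'   `"high"`/`"low"`; both classes must be present.
#' @return list of class `"rocCurve"`: `points` (data.frame cutoff, fpr,
#'   tpr) and `auc`.
#' @export
rocAuc <- function(scores, labels) {
  pos <- if (is.character(labels) || is.factor(labels))
    as.character(labels) == "high" else as.logical(labels)
  stopIfNot(any(pos) && any(!pos), "both classes must be present")
  nPos <- sum(pos); nNeg <- sum(!pos)
  rk <- rank(scores, ties.method = "average")
  auc <- (sum(rk[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  cuts <- sort(unique(scores), decreasing = TRUE)
  pts <- data.frame(
    cutoff = c(Inf, cuts),
    fpr = c(0, vapply(cuts, function(ct) mean(scores[!pos] >= ct), numeric(1))),
    tpr = c(0, vapply(cuts, function(ct) mean(scores[pos] >= ct), numeric(1))))
  structure(list(points = pts, auc = auc), class = "rocCurve")
}

#' @export
print.rocCurve <- function(x, ...) {
  cat(sprintf("ROC curve: %d cutoffs, AUC = %.4f\n",
              nrow(x$points) - 1L, x$auc))
  invisible(x)
}
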