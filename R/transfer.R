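#' Standard-to-leaf spectral similarity matrix
#'
#' For every (cultivar, concentration) pair, the Pearson correlation of the
#' two group-mean spectra restricted to the selected bands.  In the default
#' net-absorbance domain the standards are background-corrected against the
#' blank group while leaf spectra -- which have no true blank -- enter as
#' plain absorbance.  A reflectance-domain variant is available.
#'
#' @param standards concentration-labelled reflectance
#'   [SpectraTable-class].
#' @param leaves cultivar-labelled reflectance [SpectraTable-class] on the
#'   same grid.
#' @param bands a [BandSelection-class] (or indices) with >= 2 bands.
#' @param domain `"net_absorbance"` (default) or `"reflectance"`.
#' @param blankLabel blank group label of the standards.
#' @return numeric matrix, rows = cultivars, columns = concentration groups
#'   (increasing concentration), entries in `[-1, 1]`.
#' @export
similarityMatrix <- function(standards, leaves, bands,
                             domain = c("net_absorbance", "reflectance"),
                             blankLabel = "0") {
  domain <- match.arg(domain)
  idx <- if (is(bands, "BandSelection")) bands@indices else as.integer(bands)
  stopIfNot(length(idx) >= 2L, "need at least 2 bands for correlation")
  stopIfNot(isTRUE(all.equal(wavelengths(standards), wavelengths(leaves))),
            "standards and leaves must share one grid")
  if (domain == "net_absorbance") {
    std <- netAbsorbance(toAbsorbance(standards), blankLabel = blankLabel)
    lvs <- toAbsorbance(leaves)
  } else {
    std <- standards
    lvs <- leaves
  }
  concOrder <- order(vapply(unique(std@labels), function(g)
    mean(std@concentration[std@labels == g]), numeric(1)))
  concGroups <- unique(std@labels)[concOrder]
  cultivars <- unique(lvs@labels)
  stdMeans <- vapply(concGroups, function(g)
    colMeans(std@spectra[std@labels == g, idx, drop = FALSE]),
    numeric(length(idx)))
  leafMeans <- vapply(cultivars, function(g)
    colMeans(lvs@spectra[lvs@labels == g, idx, drop = FALSE]),
    numeric(length(idx)))
  out <- stats::cor(leafMeans, stdMeans)
  dimnames(out) <- list(cultivars, concGroups)
  attr(out, "bands") <- idx
  attr(out, "domain") <- domain
  out
}

#' Apply a standard-trained regressor to leaf spectra
#'
#' Predicts a concentration for every leaf spectrum from the model's bands
#' and aggregates per cultivar (median, quartiles, extrapolation counts).
#' Predictions beyond the training concentration range are retained -- they
#' are informative for relative comparison -- but counted.
#'
#' @param model a trained [CNNRegressor-class] carrying its band indices.
#' @param leaves cultivar-labelled reflectance [SpectraTable-class].
#' @param bands optional [BandSelection-class] overriding the model's
#'   stored bands.
#' @return a [TransferReport-class] (without threshold/ROC, which
#'   [dichotomizeMedian()] and [transferRoc()] add).
#' @export
transferPredict <- function(model, leaves, bands = NULL) {
  idx <- if (!is.null(bands)) {
    if (is(bands, "BandSelection")) bands@indices else as.integer(bands)
  } else model@bandIndices
  stopIfNot(length(idx) > 0L, "no band indices available")
  stopIfNot(length(idx) == model@config@nInputBands,
            "band count does not match the model input")
  X <- bandMatrix(leaves, idx)
  pred <- predict(model, X)
  extra <- attr(pred, "extrapolated")
  df <- data.frame(label = groupLabels(leaves), prediction = as.numeric(pred),
                   extrapolated = extra)
  cs <- do.call(rbind, lapply(split(df, df$label), function(d)
    data.frame(cultivar = d$label[1L], n = nrow(d),
               median = stats::median(d$prediction),
               q25 = unname(stats::quantile(d$prediction, 0.25)),
               q75 = unname(stats::quantile(d$prediction, 0.75)),
               extrapolated = sum(d$extrapolated))))
  rownames(cs) <- NULL
  new("TransferReport", predictions = df, cultivarSummary = cs,
      threshold = NA_real_, classLabels = character(0), degenerate = FALSE,
      roc = data.frame(), auc = NA_real_,
      extrapolationRange = model@trainRange)
}

#' Median dichotomization of transfer predictions
#'
#' Splits the pooled predictions at their median: strictly above the
#' threshold is `"high"`, everything else (including ties at the median)
#' `"low"` -- a deterministic, conservative tie rule.  When all predictions
#' are equal the report is flagged degenerate and everything is `"low"`.
#'
#' @param report a [TransferReport-class] from [transferPredict()].
#' @return the report with `threshold`, `classLabels` and `degenerate`
#'   filled in.
#' @export
dichotomizeMedian <- function(report) {
  p <- report@predictions$prediction
  stopIfNot(length(p) >= 2L, "need at least 2 predictions")
  thr <- stats::median(p)
  report@threshold <- thr
  report@classLabels <- ifelse(p > thr, "high", "low")
  report@degenerate <- length(unique(p)) == 1L
  report
}

#' ROC analysis of a dichotomized transfer report
#'
#' Scores are the continuous predictions themselves (the only score the
#' workflow has); labels are the median-dichotomized classes.  When no
#' prediction ties the threshold this construction yields AUC = 1 exactly.
#'
#' @param report a dichotomized [TransferReport-class].
#' @return the report with `roc` points and `auc` filled in.
#' @export
transferRoc <- function(report) {
  stopIfNot(length(report@classLabels) > 0L,
            "dichotomize the report first (dichotomizeMedian)")
  rc <- rocAuc(report@predictions$prediction, report@classLabels)
  report@roc <- rc$points
  report@auc <- rc$auc
  report
}

setMethod("show", "TransferReport", function(object) {
  cat(sprintf("TransferReport: %d predictions over %d cultivars\n",
              nrow(object@predictions), nrow(object@cultivarSummary)))
  if (!is.na(object@threshold))
    cat(sprintf("  median threshold: %.2f ug/mL; high: %d, low: %d\n",
                object@threshold, sum(object@classLabels == "high"),
                sum(object@classLabels == "low")))
  if (!is.na(object@auc)) cat(sprintf("  AUC: %.3f\n", object@auc))
})

#' Combined PCA of standards and leaves on selected bands
#'
#' Stacks the band-restricted standard and leaf spectra, runs one PCA and
#' tags every score row as `"standard"` or `"leaf"` -- the spectral-domain
#' overlap diagnostic for model transfer.
#'
#' @inheritParams similarityMatrix
#' @param nComponents retained components (default 2).
#' @return list: `pca` (a [PCAResult-class]), `set` (standard/leaf tag per
#'   row), `label` (group label per row).
#' @export
combinedPCA <- function(standards, leaves, bands, nComponents = 2L) {
  idx <- if (is(bands, "BandSelection")) bands@indices else as.integer(bands)
  stopIfNot(length(idx) >= 2L, "need at least 2 bands")
  stopIfNot(isTRUE(all.equal(wavelengths(standards), wavelengths(leaves))),
            "standards and leaves must share one grid")
  X <- rbind(bandMatrix(standards, idx), bandMatrix(leaves, idx))
  pca <- pcaSpectra(X, nComponents = nComponents)
  list(pca = pca,
       set = c(rep("standard", nrow(spectra(standards))),
               rep("leaf", nrow(spectra(leaves)))),
       label = c(groupLabels(standards), groupLabels(leaves)))
}

#' One-dimensional classification boundary figure data
#'
#' Sorted predictions with their class labels and the dashed threshold
#' line, ready for plotting; also counts label changes along the sorted
#' axis (a clean median split has exactly one crossing and zero
#' misclassifications at the threshold).
#'
#' @param report a dichotomized [TransferReport-class].
#' @return list of class `"boundarySpec"`: `data` (sorted data.frame of
#'   prediction, class, cultivar), `threshold`, `crossings`,
#'   `misclassified`, `degenerate`.
#' @export
boundaryPlot <- function(report) {
  stopIfNot(length(report@classLabels) > 0L,
            "dichotomize the report first (dichotomizeMedian)")
  if (report@degenerate)
    return(structure(list(data = data.frame(), threshold = report@threshold,
                          crossings = 0L, misclassified = 0L,
                          degenerate = TRUE), class = "boundarySpec"))
  ord <- order(report@predictions$prediction)
  df <- data.frame(prediction = report@predictions$prediction[ord],
                   class = report@classLabels[ord],
                   cultivar = report@predictions$label[ord])
  cross <- sum(df$class[-1L] != df$class[-nrow(df)])
  mis <- sum((df$prediction > report@threshold) != (df$class == "high"))
  structure(list(data = df, threshold = report@threshold,
                 crossings = cross, misclassified = mis, degenerate = FALSE),
            class = "boundarySpec")
}

#' @export
print.boundarySpec <- function(x, ...) {
  if (x$degenerate) cat("boundarySpec: degenerate (all predictions equal)\n")
  else cat(sprintf(
    "boundarySpec: %d points, threshold %.2f, %d crossing(s), %d misclassified\n",
    nrow(x$data), x$threshold, x$crossings, x$misclassified))
  invisible(x)
}
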