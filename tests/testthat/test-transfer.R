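# One moderately sized standard+leaf fixture shared across this file.
transferFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generatorConfig(seed = 19)
      std <- simulateStandardSeries(cfg)
      lvs <- simulateLeafSpectra(cfg)
      sel <- spaSelect(std, nSelect = 10)
      model <- trainCNN(bandMatrix(std, sel), concentrations(std),
                        cnnConfig(10, epochs = 50, seed = 19),
                        bandIndices = sel@indices,
                        bandWavelengths = sel@wavelengths)
      cache <<- list(cfg = cfg, std = std, lvs = lvs, sel = sel,
                     model = model)
    }
    cache
  }
})

test_that("similarity matrix has the saturation sign structure", {
  fx <- transferFixture()
  sim <- similarityMatrix(fx$std, fx$lvs, fx$sel)
  expect_true(all(sim >= -1 & sim <= 1))
  expect_identical(rownames(sim), names(fx$cfg@cultivarLoadings))
  # mid-concentration columns: positive for every cultivar; the saturated
  # top concentration flips sign for every cultivar
  for (cc in c("8", "40", "200")) expect_true(all(sim[, cc] > 0))
  expect_true(all(sim[, "1000"] < 0))
})

test_that("similarity degenerates correctly for identical and negated spectra", {
  fx <- transferFixture()
  # leaves replaced by the standards themselves: each pseudo-cultivar's
  # mean equals its own concentration column's mean -> r = 1 diagonal
  std <- fx$std
  pseudo <- spectraTable(spectra(std), generatorGrid(fx$cfg),
                         labels = paste0("cv", groupLabels(std)))
  sim <- similarityMatrix(std, pseudo, fx$sel, domain = "reflectance")
  for (g in colnames(sim))
    expect_equal(sim[paste0("cv", g), g], 1, tolerance = 1e-12)
  expect_error(similarityMatrix(std, pseudo, fx$sel@indices[1]), "2 bands")
})

test_that("transfer predictions order cultivars by their planted loadings", {
  fx <- transferFixture()
  rep <- transferPredict(fx$model, fx$lvs)
  expect_equal(nrow(rep@predictions), nrow(spectra(fx$lvs)))
  loads <- fx$cfg@cultivarLoadings[rep@cultivarSummary$cultivar]
  expect_gte(cor(rep@cultivarSummary$median, loads, method = "spearman"), 0.9)
  # the top-loading cultivar extrapolates beyond the training ceiling
  top <- which.max(loads)
  expect_gt(rep@cultivarSummary$extrapolated[top], 0)
  # single-row cultivar: median equals that prediction
  one <- spectraTable(spectra(fx$lvs)[1, , drop = FALSE],
                      generatorGrid(fx$cfg), labels = "solo")
  both <- spectraTable(spectra(fx$lvs)[1:2, , drop = FALSE],
                       generatorGrid(fx$cfg), labels = c("solo", "duo"))
  r1 <- transferPredict(fx$model, both)
  expect_equal(r1@cultivarSummary$median[r1@cultivarSummary$cultivar == "solo"],
               r1@predictions$prediction[1])
})

test_that("median dichotomization follows the conservative tie rule", {
  mk <- function(p) new("TransferReport",
    predictions = data.frame(label = "x", prediction = p,
                             extrapolated = FALSE),
    cultivarSummary = data.frame(), threshold = NA_real_,
    classLabels = character(0), degenerate = FALSE, roc = data.frame(),
    auc = NA_real_, extrapolationRange = c(0, 1000))
  r <- dichotomizeMedian(mk(c(1, 2, 3, 4)))
  expect_equal(r@threshold, 2.5)
  expect_identical(r@classLabels, c("low", "low", "high", "high"))
  # odd n: the middle value ties the median and is labelled low
  r3 <- dichotomizeMedian(mk(c(1, 2, 3)))
  expect_identical(r3@classLabels, c("low", "low", "high"))
  # degenerate: everything equal, flagged, all low
  rd <- dichotomizeMedian(mk(rep(7, 5)))
  expect_true(rd@degenerate)
  expect_true(all(rd@classLabels == "low"))
  expect_true(boundaryPlot(rd)$degenerate)
})

test_that("median-split ROC of the scores themselves yields AUC 1", {
  fx <- transferFixture()
  rep <- transferRoc(dichotomizeMedian(transferPredict(fx$model, fx$lvs)))
  expect_equal(rep@auc, 1)
  bnd <- boundaryPlot(rep)
  expect_identical(bnd$misclassified, 0L)
  expect_identical(bnd$crossings, 1L)
  expect_equal(nrow(bnd$data), nrow(rep@predictions))
})

test_that("combined PCA separates standards from leaves along PC1", {
  fx <- transferFixture()
  cp <- combinedPCA(fx$std, fx$lvs, fx$sel)
  expect_equal(length(cp$set), nrow(spectra(fx$std)) + nrow(spectra(fx$lvs)))
  pc1 <- cp$pca@scores[, 1]
  mS <- mean(pc1[cp$set == "standard"])
  mL <- mean(pc1[cp$set == "leaf"])
  # set centroids separate by much more than the replicate scatter within
  # any single concentration/cultivar group
  withinSD <- sqrt(mean(tapply(pc1, paste(cp$set, cp$label), var)))
  expect_gt(abs(mS - mL), withinSD)
  # identical sets coincide
  cpSame <- combinedPCA(fx$std, fx$std, fx$sel)
  half <- seq_len(nrow(spectra(fx$std)))
  expect_equal(mean(cpSame$pca@scores[half, 1]),
               mean(cpSame$pca@scores[-half, 1]), tolerance = 1e-8)
  # variance fractions over all components sum to 1
  full <- pcaSpectra(rbind(bandMatrix(fx$std, fx$sel),
                           bandMatrix(fx$lvs, fx$sel)))
  expect_equal(sum(full@varianceFraction), 1, tolerance = 1e-10)
})
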