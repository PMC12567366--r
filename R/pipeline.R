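# End-to-end orchestration: the standard-series workflow (stats, PCA, band
# selection, CNN cross-validation) and the standard-to-leaf transfer
# workflow, driven by one declarative configuration.

.defaultRunConfig <- function() list(
  seed = 1L,
  out = "nirband-run",
  input = list(standards = NULL, leaves = NULL, model = NULL),
  generator = list(),
  stages = list(stats = TRUE, pca = TRUE, pearson = TRUE, spa = TRUE,
                cars = TRUE, cnn = TRUE, falsecolor = FALSE),
  selection = list(pearsonThreshold = 0.6, spaBands = 10L,
                   carsRuns = 50L, carsRetention = 0.1,
                   carsComponents = 10L, carsSubsample = 0.8),
  cnn = list(epochs = 300L, batchSize = 16L, learningRate = 1e-3,
             folds = 5L))

.mergeConfig <- function(defaults, user, path = "") {
  for (k in names(user)) {
    if (identical(path, "") && k == "generator") {
      # generator overrides mirror generatorConfig()'s arguments
      bad <- setdiff(names(user[[k]]), names(formals(generatorConfig)))
      if (length(bad))
        stop("unknown config key: generator.", bad[1L], call. = FALSE)
      defaults[[k]] <- as.list(user[[k]])
      next
    }
    if (!k %in% names(defaults))
      stop("unknown config key: ", paste0(path, k), call. = FALSE)
    if (is.list(defaults[[k]]) && !is.null(user[[k]]))
      defaults[[k]] <- .mergeConfig(defaults[[k]], as.list(user[[k]]),
                                    paste0(path, k, "."))
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Read and validate a run configuration
#'
#' Configurations are flat declarative YAML mirroring the workflow
#' parameters (seed, generator overrides, stage toggles, selector and
#' network settings).  Unknown keys are rejected; omitted keys take the
#' package defaults.  `runConfig()` builds the same structure from R
#' arguments.
#'
#' @param path YAML file path.
#' @param ... for `runConfig`: named overrides of the default structure.
#' @return a validated nested list.
#' @export
readRunConfig <- function(path) {
  .mergeConfig(.defaultRunConfig(), yaml::read_yaml(path))
}

#' @rdname readRunConfig
#' @export
runConfig <- function(...) .mergeConfig(.defaultRunConfig(), list(...))

.stage <- function(name, log, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  cat(sprintf("[%s] %.2fs\n", name, proc.time()[["elapsed"]] - t0),
      file = log, append = TRUE)
  res
}

.logLine <- function(log, fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                        file = log, append = TRUE)

.digestArtifacts <- function(outDir, log) {
  files <- setdiff(list.files(outDir, recursive = TRUE, full.names = TRUE),
                   file.path(outDir, "run.log"))
  for (f in files)
    .logLine(log, "artifact %s md5 %s", basename(f),
             unname(tools::md5sum(f)))
}

.generatorFromConfig <- function(config) {
  args <- config$generator
  args$seed <- config$seed
  do.call(generatorConfig, args)
}

.loadStandards <- function(config) {
  if (!is.null(config$input$standards)) readSpectraCSV(config$input$standards)
  else simulateStandardSeries(.generatorFromConfig(config))
}

.loadLeaves <- function(config) {
  if (!is.null(config$input$leaves)) readSpectraCSV(config$input$leaves)
  else simulateLeafSpectra(.generatorFromConfig(config))
}

#' Run the standard-series workflow
#'
#' In order: per-group repeatability statistics with the CV report, PCA of
#' the full reflectance table, the enabled band selections (Pearson filter,
#' successive projections, competitive adaptive reweighted sampling) with
#' their selection tables, cross-validated 1-D CNN metrics per selector,
#' an optional false-color map of a simulated scene at the top selected
#' band, and a model directory holding the network trained on the full
#' standard series with the primary (SPA) bands.  Every artifact is written
#' under `config$out` and is bit-identical across reruns of the same
#' `(config, seed)`.
#'
#' @param config a [runConfig()] / [readRunConfig()] list.
#' @return invisible list with the in-memory results (`standards`,
#'   `stats`, `pca`, `selections`, `metrics`, `model`, `outDir`).
#' @export
runStandardWorkflow <- function(config) {
  outDir <- config$out
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(outDir, "run.log")
  cat(sprintf("standard workflow; seed %d\n", config$seed), file = log)
  yaml::write_yaml(config, file.path(outDir, "config.yaml"))
  standards <- .stage("input", log, .loadStandards(config))
  .logLine(log, "standards: %d x %d", nrow(spectra(standards)),
           nBands(standards))
  stats <- pca <- NULL
  if (isTRUE(config$stages$stats)) {
    stats <- .stage("stats", log, groupStats(standards))
    writeGroupStatsCSV(stats, file.path(outDir, "group_stats.csv"))
  }
  if (isTRUE(config$stages$pca)) {
    pca <- .stage("pca", log, pcaSpectra(standards, nComponents = 2L))
    utils::write.csv(
      data.frame(label = groupLabels(standards),
                 pc1 = pca@scores[, 1L], pc2 = pca@scores[, 2L]),
      file.path(outDir, "pca_scores.csv"), row.names = FALSE)
  }
  selections <- list()
  if (isTRUE(config$stages$pearson))
    selections$pearson <- .stage("select-pearson", log,
      pearsonSelect(standards, threshold = config$selection$pearsonThreshold))
  if (isTRUE(config$stages$spa))
    selections$spa <- .stage("select-spa", log,
      spaSelect(standards, nSelect = config$selection$spaBands))
  if (isTRUE(config$stages$cars))
    selections$cars <- .stage("select-cars", log,
      carsSelect(standards, nRuns = config$selection$carsRuns,
                 finalRetention = config$selection$carsRetention,
                 plsComponents = config$selection$carsComponents,
                 subsample = config$selection$carsSubsample,
                 seed = config$seed))
  for (nm in names(selections))
    writeBandSelectionCSV(selections[[nm]],
                          file.path(outDir, sprintf("selection_%s.csv", nm)))
  metrics <- NULL
  model <- NULL
  if (isTRUE(config$stages$cnn) && length(selections)) {
    rows <- list()
    for (nm in names(selections)) {
      sel <- selections[[nm]]
      if (length(sel@indices) < 5L) {
        .logLine(log, "cnn-%s skipped: %d band(s) < kernel width", nm,
                 length(sel@indices))
        next
      }
      cv <- .stage(paste0("cnn-", nm), log, cnnCrossValidate(
        standards, k = config$cnn$folds, bands = sel,
        config = cnnConfig(length(sel@indices),
                           epochs = config$cnn$epochs,
                           batchSize = config$cnn$batchSize,
                           learningRate = config$cnn$learningRate,
                           seed = config$seed),
        seed = config$seed))
      rows[[nm]] <- data.frame(selector = nm, nBands = length(sel@indices),
                               r2 = cv$metrics@r2, rmse = cv$metrics@rmse,
                               rpd = cv$metrics@rpd)
    }
    metrics <- do.call(rbind, rows)
    if (!is.null(metrics)) {
      rownames(metrics) <- NULL
      utils::write.csv(metrics, file.path(outDir, "cnn_metrics.csv"),
                       row.names = FALSE)
    }
    primary <- if (!is.null(selections$spa)) selections$spa else
      selections[[1L]]
    if (length(primary@indices) >= 5L) {
      model <- .stage("train-final", log, trainCNN(
        bandMatrix(standards, primary), concentrations(standards),
        cnnConfig(length(primary@indices), epochs = config$cnn$epochs,
                  batchSize = config$cnn$batchSize,
                  learningRate = config$cnn$learningRate,
                  seed = config$seed),
        bandIndices = primary@indices,
        bandWavelengths = primary@wavelengths))
      saveCNN(model, file.path(outDir, "model"))
    }
  }
  if (isTRUE(config$stages$falsecolor) && length(selections)) {
    primary <- if (!is.null(selections$spa)) selections$spa else
      selections[[1L]]
    topBand <- primary@wavelengths[which.max(primary@diagnostics$pearson$abs_r)]
    gen <- .generatorFromConfig(config)
    scn <- sceneSpec(8L, 12L, background = 0.05, patches = list(
      scenePatch(2:7, 2:5, 0.3), scenePatch(2:7, 8:11, 0.7)))
    tripl <- simulateRawCube(gen, scn)
    cube <- radiometricCorrect(tripl$raw, tripl$dark, tripl$white)
    fc <- .stage("falsecolor", log, falseColorBandMap(cube, topBand))
    writeFalseColorPNG(fc, file.path(outDir, "falsecolor.png"))
  }
  .digestArtifacts(outDir, log)
  invisible(list(standards = standards, stats = stats, pca = pca,
                 selections = selections, metrics = metrics, model = model,
                 outDir = outDir))
}

#' Run the standard-to-leaf transfer workflow
#'
#' Loads (or takes) a trained model, predicts concentrations for the leaf
#' spectra on the model's bands, and produces the transfer diagnostics:
#' the standard/leaf similarity matrix, per-cultivar prediction summaries,
#' the combined PCA, the median threshold with class labels, the ROC curve
#' with its AUC, and the boundary figure data.
#'
#' @param config a [runConfig()] list; `config$input$model` may name a
#'   model directory saved by the standard workflow.
#' @param model optional [CNNRegressor-class] overriding
#'   `config$input$model`.
#' @return invisible list with `report` (a [TransferReport-class]),
#'   `similarity`, `combinedPca`, `boundary` and `outDir`.
#' @export
runTransferWorkflow <- function(config, model = NULL) {
  outDir <- config$out
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(outDir, "run.log")
  cat(sprintf("transfer workflow; seed %d\n", config$seed), file = log)
  yaml::write_yaml(config, file.path(outDir, "config.yaml"))
  if (is.null(model)) {
    stopIfNot(!is.null(config$input$model),
              "no model: set config$input$model or pass one")
    model <- .stage("load-model", log, loadCNN(config$input$model))
  }
  standards <- .stage("input-standards", log, .loadStandards(config))
  leaves <- .stage("input-leaves", log, .loadLeaves(config))
  .logLine(log, "leaves: %d x %d", nrow(spectra(leaves)), nBands(leaves))
  sim <- .stage("similarity", log,
                similarityMatrix(standards, leaves, model@bandIndices))
  utils::write.csv(as.data.frame(sim), file.path(outDir, "similarity.csv"))
  report <- .stage("predict", log, transferPredict(model, leaves))
  report <- dichotomizeMedian(report)
  report <- transferRoc(report)
  utils::write.csv(report@predictions,
                   file.path(outDir, "leaf_predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(report@cultivarSummary,
                   file.path(outDir, "cultivar_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report@roc, file.path(outDir, "roc_points.csv"),
                   row.names = FALSE)
  cp <- .stage("combined-pca", log,
               combinedPCA(standards, leaves, model@bandIndices))
  utils::write.csv(
    data.frame(set = cp$set, label = cp$label,
               pc1 = cp$pca@scores[, 1L], pc2 = cp$pca@scores[, 2L]),
    file.path(outDir, "combined_pca.csv"), row.names = FALSE)
  bnd <- boundaryPlot(report)
  if (!bnd$degenerate)
    utils::write.csv(bnd$data, file.path(outDir, "boundary.csv"),
                     row.names = FALSE)
  jsonlite::write_json(list(
    threshold = report@threshold, auc = report@auc,
    degenerate = report@degenerate,
    extrapolated = sum(report@predictions$extrapolated),
    cultivars = report@cultivarSummary), file.path(outDir, "report.json"),
    auto_unbox = TRUE, digits = 10, dataframe = "rows")
  .digestArtifacts(outDir, log)
  invisible(list(report = report, similarity = sim, combinedPca = cp,
                 boundary = bnd, outDir = outDir))
}
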