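# A small 1-D convolutional regressor for band-selected spectra, written
# against base R numerics.  Architecture (valid convolution, floor pooling):
#   input (p bands) -> conv1d (filters x kernel, ReLU) -> max-pool (pool)
#   -> flatten -> dense (denseUnits, ReLU) -> linear output (1)
# trained with mean squared error and an adaptive-moment optimizer.  The
# network is deliberately tiny (a few thousand parameters for 10 input
# bands), so CPU training is fast and exactly reproducible.

#' Configuration for the 1-D convolutional regressor
#'
#' @param nInputBands number of input bands (>= kernel).
#' @param filters,kernel,pool,denseUnits architecture sizes (defaults
#'   64/5/2/32).
#' @param epochs,batchSize,learningRate training hyperparameters (defaults
#'   300/16/1e-3; mean squared error loss, adaptive-moment optimizer, no
#'   early stopping so runs are deterministic).
#' @param seed seed for initialization and shuffling.
#' @param scaleTarget z-score the target during training (inverted at
#'   prediction); stabilizes optimization over a 0--1000 ug/mL range.
#' @return a validated [CNNConfig-class].
#' @export
cnnConfig <- function(nInputBands, filters = 64L, kernel = 5L, pool = 2L,
                      denseUnits = 32L, epochs = 300L, batchSize = 16L,
                      learningRate = 1e-3, seed = 1L, scaleTarget = TRUE) {
  new("CNNConfig", nInputBands = as.integer(nInputBands),
      filters = as.integer(filters), kernel = as.integer(kernel),
      pool = as.integer(pool), denseUnits = as.integer(denseUnits),
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      learningRate = learningRate, seed = as.integer(seed),
      scaleTarget = isTRUE(scaleTarget))
}

#' Layer dimensions and parameter count of a configuration
#'
#' `cnnDimensions` gives the valid-convolution output length, the pooled
#' length (floor) and the flattened width; `cnnParameterCount` the total
#' number of learnable parameters:
#' `filters*(kernel+1) + flat*denseUnits + denseUnits + denseUnits + 1`.
#'
#' @param config a [CNNConfig-class].
#' @return `cnnDimensions`: list(convLen, poolLen, flatLen);
#'   `cnnParameterCount`: integer.
#' @export
cnnDimensions <- function(config) {
  convLen <- config@nInputBands - config@kernel + 1L
  poolLen <- convLen %/% config@pool
  list(convLen = convLen, poolLen = poolLen,
       flatLen = poolLen * config@filters)
}

#' @rdname cnnDimensions
#' @export
cnnParameterCount <- function(config) {
  d <- cnnDimensions(config)
  config@filters * (config@kernel + 1L) +
    d$flatLen * config@denseUnits + config@denseUnits +
    config@denseUnits + 1L
}

# Seeded parameter initialization (He-style scaling).
.cnnInit <- function(config) {
  d <- cnnDimensions(config)
  withSeed(stageSeed(config@seed, "cnn"), list(
    K = matrix(stats::rnorm(config@filters * config@kernel,
                            sd = sqrt(2 / config@kernel)),
               config@filters, config@kernel),
    bK = numeric(config@filters),
    W1 = matrix(stats::rnorm(d$flatLen * config@denseUnits,
                             sd = sqrt(2 / d$flatLen)),
                d$flatLen, config@denseUnits),
    b1 = numeric(config@denseUnits),
    W2 = matrix(stats::rnorm(config@denseUnits,
                             sd = sqrt(1 / config@denseUnits)),
                config@denseUnits, 1L),
    b2 = 0))
}

# Forward pass on a standardized batch; returns activations for backprop.
.cnnForward <- function(params, X, config) {
  d <- cnnDimensions(config)
  n <- nrow(X); nf <- config@filters
  Z <- array(0, c(n, nf, d$convLen))
  for (j in seq_len(d$convLen))
    Z[, , j] <- X[, j:(j + config@kernel - 1L), drop = FALSE] %*%
      t(params$K) + rep(params$bK, each = n)
  A <- pmax(Z, 0)
  P <- array(0, c(n, nf, d$poolLen))
  winner <- array(1L, c(n, nf, d$poolLen))  # offset within the pool window
  for (m in seq_len(d$poolLen)) {
    base <- (m - 1L) * config@pool
    best <- A[, , base + 1L]
    if (config@pool >= 2L) for (o in 2L:config@pool) {
      cand <- A[, , base + o]
      upd <- cand > best
      best[upd] <- cand[upd]
      winner[, , m][upd] <- o
    }
    P[, , m] <- best
  }
  Fm <- P; dim(Fm) <- c(n, d$flatLen)
  Hpre <- Fm %*% params$W1 + rep(params$b1, each = n)
  H <- pmax(Hpre, 0)
  yhat <- drop(H %*% params$W2) + params$b2
  list(Z = Z, winner = winner, Fm = Fm, H = H, yhat = yhat)
}

# Gradients of the batch MSE loss.
.cnnBackward <- function(params, X, y, fwd, config) {
  d <- cnnDimensions(config)
  n <- nrow(X); nf <- config@filters
  dy <- matrix(2 * (fwd$yhat - y) / n, n, 1L)
  dW2 <- crossprod(fwd$H, dy)
  db2 <- sum(dy)
  dH <- dy %*% t(params$W2)
  dH[fwd$H <= 0] <- 0
  dW1 <- crossprod(fwd$Fm, dH)
  db1 <- colSums(dH)
  dF <- dH %*% t(params$W1)
  dim(dF) <- c(n, nf, d$poolLen)
  dZ <- array(0, c(n, nf, d$convLen))
  for (m in seq_len(d$poolLen)) {
    base <- (m - 1L) * config@pool
    for (o in seq_len(config@pool))
      dZ[, , base + o] <- dF[, , m] * (fwd$winner[, , m] == o)
  }
  dZ[fwd$Z <= 0] <- 0
  dK <- matrix(0, nf, config@kernel)
  dbK <- numeric(nf)
  for (j in seq_len(d$convLen)) {
    dzj <- dZ[, , j, drop = FALSE]; dim(dzj) <- c(n, nf)
    dK <- dK + crossprod(dzj, X[, j:(j + config@kernel - 1L), drop = FALSE])
    dbK <- dbK + colSums(dzj)
  }
  list(K = dK, bK = dbK, W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

#' Train the 1-D convolutional regressor
#'
#' Standardizes inputs per band and (optionally) z-scores the target using
#' the training rows only, then runs seeded mini-batch gradient descent
#' with adaptive moments.  Training is bit-reproducible for a fixed
#' `(config, data)` on one compute device.
#'
#' @param x numeric matrix of band-selected spectra (rows = samples), with
#'   `ncol(x) == config@nInputBands`.
#' @param y numeric target (concentration, ug/mL).
#' @param config a [CNNConfig-class].
#' @param bandIndices,bandWavelengths optional provenance of the input
#'   bands, stored in the model.
#' @return a [CNNRegressor-class].
#' @export
trainCNN <- function(x, y, config, bandIndices = integer(0),
                     bandWavelengths = numeric(0)) {
  X <- as.matrix(x)
  validObject(config)
  stopIfNot(ncol(X) == config@nInputBands,
            "ncol(x) must equal config@nInputBands")
  stopIfNot(nrow(X) == length(y), "x and y size mismatch")
  xm <- colMeans(X)
  xs <- apply(X, 2L, stats::sd)
  xs[xs == 0] <- 1
  Xs <- sweep(sweep(X, 2L, xm), 2L, xs, "/")
  if (config@scaleTarget) {
    ym <- mean(y); ys <- stats::sd(y); if (!is.finite(ys) || ys == 0) ys <- 1
  } else { ym <- 0; ys <- 1 }
  yt <- (y - ym) / ys
  params <- .cnnInit(config)
  mom <- lapply(params, function(p) p * 0)
  vel <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  step <- 0L
  trace <- numeric(config@epochs)
  withSeed(stageSeed(config@seed, "cnn") + 1L, {
    n <- nrow(Xs)
    for (ep in seq_len(config@epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config@batchSize)
      lossSum <- 0
      for (s in starts) {
        rows <- ord[s:min(s + config@batchSize - 1L, n)]
        Xb <- Xs[rows, , drop = FALSE]
        yb <- yt[rows]
        fwd <- .cnnForward(params, Xb, config)
        lossSum <- lossSum + sum((fwd$yhat - yb)^2)
        grads <- .cnnBackward(params, Xb, yb, fwd, config)
        step <- step + 1L
        for (nm in names(params)) {
          mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * grads[[nm]]
          vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * grads[[nm]]^2
          mhat <- mom[[nm]] / (1 - b1^step)
          vhat <- vel[[nm]] / (1 - b2^step)
          params[[nm]] <- params[[nm]] -
            config@learningRate * mhat / (sqrt(vhat) + epsA)
        }
      }
      trace[ep] <- lossSum / n
    }
  })
  new("CNNRegressor", config = config, params = params,
      xCenter = xm, xScale = xs, yCenter = ym, yScale = ys,
      lossTrace = trace, bandIndices = as.integer(bandIndices),
      bandWavelengths = as.numeric(bandWavelengths),
      trainRange = range(y))
}

#' Predict concentrations from a trained regressor
#'
#' Applies the stored standardization, runs the forward pass and inverts
#' the target scaling.  Predictions outside the training concentration
#' range are returned unchanged but flagged (attribute `"extrapolated"`).
#'
#' @param object a [CNNRegressor-class].
#' @param newdata matrix with the model's input band count.
#' @param ... ignored.
#' @return numeric predictions (ug/mL) with a logical `"extrapolated"`
#'   attribute.
#' @export
setMethod("predict", "CNNRegressor", function(object, newdata, ...) {
  X <- as.matrix(newdata)
  stopIfNot(ncol(X) == object@config@nInputBands,
            "band-count mismatch: model expects ",
            object@config@nInputBands, " bands")
  Xs <- sweep(sweep(X, 2L, object@xCenter), 2L, object@xScale, "/")
  out <- .cnnForward(object@params, Xs, object@config)$yhat *
    object@yScale + object@yCenter
  attr(out, "extrapolated") <-
    out < object@trainRange[1L] | out > object@trainRange[2L]
  out
})

setMethod("show", "CNNRegressor", function(object) {
  cat(sprintf("CNNRegressor: %d input bands, %d parameters, %d epochs (final loss %.4g)\n",
              object@config@nInputBands, cnnParameterCount(object@config),
              object@config@epochs,
              object@lossTrace[length(object@lossTrace)]))
})

#' Seeded stratified cross-validation of the regressor
#'
#' Folds are stratified by group label so every fold spans the full
#' concentration range; the assignment is a seeded within-group shuffle
#' followed by cyclic allocation.  Per fold, inputs are standardized on the
#' training rows only, the network is trained, and held-out rows are
#' predicted; all out-of-fold predictions are pooled for the headline
#' metrics (per-fold metrics are attached).
#'
#' @param x matrix of band-selected spectra or a [SpectraTable-class]
#'   restricted via `bands`.
#' @param y response; defaults to the table's concentrations.
#' @param k folds (default 5); every group needs at least `k` rows.
#' @param config a [CNNConfig-class]; defaults to `cnnConfig(ncol(x))`.
#' @param bands optional [BandSelection-class] applied to a table input.
#' @param groups optional stratification labels (default: the table's
#'   labels, or `factor(y)`).
#' @param seed seed of the fold-assignment stream.
#' @return list with `metrics` (pooled [RegressionMetrics-class] with
#'   per-fold rows), `predictions` (out-of-fold, in input order), `folds`
#'   (assignment) and `models` (per-fold [CNNRegressor-class]s).
#' @export
cnnCrossValidate <- function(x, y = NULL, k = 5L, config = NULL,
                             bands = NULL, groups = NULL, seed = 1L) {
  if (is(x, "SpectraTable")) {
    if (is.null(y)) y <- concentrations(x)
    if (is.null(groups)) groups <- groupLabels(x)
    X <- if (is.null(bands)) spectra(x) else bandMatrix(x, bands)
  } else X <- as.matrix(x)
  stopIfNot(!is.null(y), "a response is required")
  if (is.null(groups)) groups <- as.character(y)
  if (is.null(config)) config <- cnnConfig(ncol(X))
  k <- as.integer(k)
  stopIfNot(k >= 2L, "k must be >= 2")
  tab <- table(groups)
  if (any(tab < k))
    stop("stratification error: group(s) with fewer than k rows: ",
         paste(names(tab)[tab < k], collapse = ", "), call. = FALSE)
  folds <- integer(length(y))
  withSeed(stageSeed(seed, "folds"), {
    for (g in names(tab)) {
      idx <- which(groups == g)
      folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  })
  preds <- numeric(length(y))
  models <- vector("list", k)
  foldRows <- data.frame(fold = integer(0), r2 = numeric(0),
                         rmse = numeric(0), rpd = numeric(0))
  for (f in seq_len(k)) {
    tr <- folds != f
    cfg <- config
    cfg@seed <- as.integer(config@seed + f)  # independent init per fold
    models[[f]] <- trainCNN(X[tr, , drop = FALSE], y[tr], cfg)
    ph <- predict(models[[f]], X[!tr, , drop = FALSE])
    preds[!tr] <- as.numeric(ph)
    fm <- tryCatch(regressionMetrics(y[!tr], as.numeric(ph)),
                   error = function(e) NULL)
    if (!is.null(fm))
      foldRows <- rbind(foldRows, data.frame(fold = f, r2 = fm@r2,
                                             rmse = fm@rmse, rpd = fm@rpd))
  }
  metrics <- regressionMetrics(y, preds, folds = foldRows)
  list(metrics = metrics, predictions = preds, folds = folds, models = models)
}

#' Save / load a trained regressor as plain text
#'
#' The model directory holds `params.json` (all weights at full precision)
#' and `model_info.txt`, a human-readable sidecar with the architecture,
#' standardization vectors, band provenance and seed -- everything needed
#' to reload and predict bit-reproducibly.
#'
#' @param model a [CNNRegressor-class].
#' @param dir model directory (created if missing).
#' @return `saveCNN`: `dir` invisibly; `loadCNN`: a [CNNRegressor-class].
#' @export
saveCNN <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model@config
  full <- function(v) sprintf("%.17g", as.numeric(v))  # bit-exact reload
  payload <- list(
    config = list(nInputBands = cfg@nInputBands, filters = cfg@filters,
                  kernel = cfg@kernel, pool = cfg@pool,
                  denseUnits = cfg@denseUnits, epochs = cfg@epochs,
                  batchSize = cfg@batchSize, learningRate = cfg@learningRate,
                  seed = cfg@seed, scaleTarget = cfg@scaleTarget),
    params = lapply(model@params, function(p)
      list(dim = dim(p), values = full(p))),
    xCenter = full(model@xCenter), xScale = full(model@xScale),
    yCenter = full(model@yCenter), yScale = full(model@yScale),
    lossTrace = full(model@lossTrace), bandIndices = model@bandIndices,
    bandWavelengths = model@bandWavelengths,
    trainRange = full(model@trainRange))
  jsonlite::write_json(payload, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(
    sprintf("input bands: %d", cfg@nInputBands),
    sprintf("architecture: conv(%d x %d, relu) -> maxpool(%d) -> dense(%d, relu) -> linear(1)",
            cfg@filters, cfg@kernel, cfg@pool, cfg@denseUnits),
    sprintf("parameters: %d", cnnParameterCount(cfg)),
    sprintf("epochs: %d  batch: %d  lr: %g  seed: %d",
            cfg@epochs, cfg@batchSize, cfg@learningRate, cfg@seed),
    sprintf("band wavelengths (nm): %s",
            paste(sprintf("%.1f", model@bandWavelengths), collapse = ", ")),
    sprintf("training target range: %g..%g ug/mL",
            model@trainRange[1L], model@trainRange[2L])),
    file.path(dir, "model_info.txt"))
  invisible(dir)
}

#' @rdname saveCNN
#' @export
loadCNN <- function(dir) {
  payload <- jsonlite::read_json(file.path(dir, "params.json"),
                                 simplifyVector = TRUE)
  cfgL <- payload$config
  cfg <- cnnConfig(cfgL$nInputBands, cfgL$filters, cfgL$kernel, cfgL$pool,
                   cfgL$denseUnits, cfgL$epochs, cfgL$batchSize,
                   cfgL$learningRate, cfgL$seed, cfgL$scaleTarget)
  params <- lapply(payload$params, function(p) {
    v <- as.numeric(p$values)
    if (length(p$dim)) dim(v) <- p$dim
    v
  })
  params$b2 <- as.numeric(params$b2)
  new("CNNRegressor", config = cfg, params = params,
      xCenter = as.numeric(payload$xCenter),
      xScale = as.numeric(payload$xScale),
      yCenter = as.numeric(payload$yCenter),
      yScale = as.numeric(payload$yScale),
      lossTrace = as.numeric(payload$lossTrace),
      bandIndices = as.integer(payload$bandIndices),
      bandWavelengths = as.numeric(payload$bandWavelengths),
      trainRange = as.numeric(payload$trainRange))
}
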