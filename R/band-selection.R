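# Wavelength selection: Pearson filter, successive projections algorithm
# (SPA) and competitive adaptive reweighted sampling (CARS).

# Resolve (X, y, wavelengths) from a SpectraTable or a plain matrix.
.selectionInput <- function(x, y) {
  if (is(x, "SpectraTable")) {
    if (is.null(y)) y <- concentrations(x)
    stopIfNot(!is.null(y), "no response: table has no concentrations")
    list(X = spectra(x), y = y, wl = wavelengths(x))
  } else {
    X <- as.matrix(x)
    stopIfNot(!is.null(y), "y is required for matrix input")
    wl <- suppressWarnings(as.numeric(colnames(X)))
    if (any(is.na(wl)) || is.null(colnames(X))) wl <- seq_len(ncol(X))
    list(X = X, y = y, wl = wl)
  }
}

.selectionDiagnostics <- function(X, y, idx, wl) {
  r <- columnPearson(X[, idx, drop = FALSE], y)$r
  data.frame(wavelength = wl[idx], r = r, abs_r = abs(r))
}

#' Per-band Pearson correlation with concentration
#'
#' Sample Pearson correlation of every band with the response, the
#' tabulated diagnostic attached to all band selections.  Zero-variance
#' bands are flagged and reported with `r = 0`.
#'
#' @param x a concentration-labelled [SpectraTable-class], or a matrix.
#' @param y response vector (defaults to the table's concentrations).
#' @return data.frame with `band`, `wavelength`, `r`, `abs_r`, `flagged`.
#' @export
pearsonTable <- function(x, y = NULL) {
  inp <- .selectionInput(x, y)
  res <- columnPearson(inp$X, inp$y)
  data.frame(band = seq_len(ncol(inp$X)), wavelength = inp$wl,
             r = res$r, abs_r = abs(res$r), flagged = res$flagged)
}

#' Pearson-filter band selection
#'
#' Retains every band whose absolute correlation with the response strictly
#' exceeds `threshold`, ordered by `|r|` descending.  An empty selection is
#' legal (returned with zero bands).
#'
#' @inheritParams pearsonTable
#' @param threshold absolute-correlation cutoff (default 0.6).
#' @return a [BandSelection-class] with method `"pearson"`.
#' @export
pearsonSelect <- function(x, y = NULL, threshold = 0.6) {
  inp <- .selectionInput(x, y)
  tab <- pearsonTable(x, y)
  keep <- tab[!tab$flagged & tab$abs_r > threshold, ]
  keep <- keep[order(-keep$abs_r), ]
  idx <- as.integer(keep$band)
  new("BandSelection", method = "pearson", indices = idx,
      wavelengths = inp$wl[idx],
      diagnostics = list(
        pearson = .selectionDiagnostics(inp$X, inp$y, idx, inp$wl),
        threshold = threshold, nCandidates = ncol(inp$X)))
}

# Deterministic interleaved fold assignment; rows arrive grouped by
# concentration so interleaving spreads every group over all folds.
.interleavedFolds <- function(n, k) rep_len(seq_len(k), n)

# Canonical row order (response, then leading predictor columns): makes the
# selectors invariant to row permutation of their input.
.canonicalOrder <- function(X, y) {
  keys <- c(list(y), lapply(seq_len(min(3L, ncol(X))),
                            function(j) X[, j]))
  do.call(order, keys)
}

# Cross-validated RMSE of ordinary least squares on a fixed band set.
.olsCvRmse <- function(X, y, idx, nFolds = 5L) {
  folds <- .interleavedFolds(length(y), nFolds)
  press <- 0
  for (f in seq_len(nFolds)) {
    tr <- folds != f
    Xt <- cbind(1, X[tr, idx, drop = FALSE])
    fit <- stats::lm.fit(Xt, y[tr])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    pred <- cbind(1, X[!tr, idx, drop = FALSE]) %*% beta
    press <- press + sum((y[!tr] - pred)^2)
  }
  sqrt(press / length(y))
}

# One deterministic SPA chain from a given start on centred columns.
.spaChain <- function(Xc, start, nSelect) {
  E <- Xc
  chain <- integer(nSelect)
  norms <- numeric(nSelect)
  chain[1L] <- start
  norms[1L] <- sum(E[, start]^2)
  for (s in seq_len(nSelect - 1L)) {
    u <- E[, chain[s]]
    uu <- sum(u^2)
    if (uu <= 1e-12) return(list(chain = chain[seq_len(s)], norms = norms))
    E <- E - u %*% (crossprod(u, E) / uu)
    cn <- colSums(E^2)
    cn[chain[seq_len(s)]] <- -1
    nxt <- which.max(cn)
    if (cn[nxt] <= 1e-12) return(list(chain = chain[seq_len(s)], norms = norms))
    chain[s + 1L] <- nxt
    norms[s + 1L] <- cn[nxt]
  }
  list(chain = chain, norms = norms)
}

#' Successive projections algorithm
#'
#' Builds, for every candidate starting band, a chain of maximally
#' non-collinear bands: after mean-centring the columns, each step picks
#' the column of largest norm after projection onto the orthogonal
#' complement of the span of the columns already chosen.  The response
#' plays no role in chain construction; chains are then scored by
#' cross-validated RMSE of an ordinary least squares fit on the chain's
#' bands, and the best chain wins.  Ties are broken by smaller mean
#' absolute inter-band correlation (less redundancy), then by lower first
#' band index.  The procedure is fully deterministic.
#'
#' @inheritParams pearsonTable
#' @param nSelect number of bands to select (default 10).
#' @param nFolds folds for the OLS scoring (default 5).
#' @return a [BandSelection-class] with method `"spa"`; diagnostics carry
#'   the winning start, per-step projection norms and the scoring table.
#' @export
spaSelect <- function(x, y = NULL, nSelect = 10L, nFolds = 5L) {
  inp <- .selectionInput(x, y)
  ord <- .canonicalOrder(inp$X, inp$y)
  X <- inp$X[ord, , drop = FALSE]; yv <- inp$y[ord]
  p <- ncol(X); n <- nrow(X)
  nSelect <- as.integer(nSelect)
  stopIfNot(nSelect >= 1L, "nSelect must be >= 1")
  stopIfNot(nSelect <= n - 2L, "nSelect must be <= nrow - 2")
  Xc <- sweep(X, 2L, colMeans(X))
  chains <- vector("list", p)
  ok <- logical(p)
  for (j in seq_len(p)) {
    ch <- .spaChain(Xc, j, nSelect)
    chains[[j]] <- ch
    ok[j] <- length(ch$chain) == nSelect
  }
  if (!any(ok)) {
    best <- max(vapply(chains, function(ch) length(ch$chain), integer(1)))
    stop("rank deficiency: longest achievable chain has ", best,
         " bands (requested ", nSelect, ")", call. = FALSE)
  }
  scores <- rep(Inf, p)
  for (j in which(ok))
    scores[j] <- .olsCvRmse(X, yv, chains[[j]]$chain, nFolds)
  bestScore <- min(scores)
  cand <- which(scores <= bestScore + 1e-12)
  if (length(cand) > 1L) {  # tie-break: redundancy, then first band index
    red <- vapply(cand, function(j) {
      C <- abs(stats::cor(X[, chains[[j]]$chain, drop = FALSE]))
      mean(C[upper.tri(C)])
    }, numeric(1))
    cand <- cand[red == min(red)]
    cand <- cand[which.min(vapply(cand, function(j) chains[[j]]$chain[1L],
                                  integer(1)))]
  }
  win <- chains[[cand[1L]]]
  idx <- as.integer(win$chain)
  new("BandSelection", method = "spa", indices = idx,
      wavelengths = inp$wl[idx],
      diagnostics = list(
        pearson = .selectionDiagnostics(X, yv, idx, inp$wl),
        start = cand[1L], projectionNorms = win$norms,
        cvRmse = bestScore, scores = scores))
}

#' Competitive adaptive reweighted sampling
#'
#' Monte-Carlo band selection driven by partial least squares regression
#' coefficients.  Each run fits a PLS model on a random row subsample of
#' the currently active bands, ranks bands by `|b|`, deterministically
#' keeps the top `N_i` bands of an exponentially decreasing schedule (all
#' bands at run 1 down to `ceiling(finalRetention * p)` at the last run),
#' and then applies adaptive reweighted sampling -- `N_i` weighted draws
#' with replacement, the unique survivors forming the next active set.
#' Every run's active set is scored by cross-validated PLS RMSE; the
#' minimal-RMSE set wins.
#'
#' @inheritParams pearsonTable
#' @param nRuns Monte-Carlo runs (default 50).
#' @param finalRetention fraction of the original bands retained by the
#'   schedule at the last run (default 0.10).
#' @param plsComponents ceiling on PLS components (default 10; capped by
#'   the data's rank limits).
#' @param subsample row fraction drawn (without replacement) per run.
#' @param seed seed of the dedicated CARS random stream.
#' @param schedule `"exponential"` (standard CARS, final retention reached
#'   at the last run) or `"per_iteration"` (keep `1 - finalRetention` of
#'   the active bands each run).
#' @return a [BandSelection-class] with method `"cars"`; diagnostics carry
#'   per-run RMSE, retained counts and the schedule.
#' @export
carsSelect <- function(x, y = NULL, nRuns = 50L, finalRetention = 0.10,
                       plsComponents = 10L, subsample = 0.8, seed = 1L,
                       schedule = c("exponential", "per_iteration")) {
  schedule <- match.arg(schedule)
  inp <- .selectionInput(x, y)
  ord <- .canonicalOrder(inp$X, inp$y)
  X <- inp$X[ord, , drop = FALSE]; yv <- inp$y[ord]
  p <- ncol(X); n <- nrow(X)
  stopIfNot(nRuns >= 2L, "nRuns must be >= 2")
  stopIfNot(finalRetention > 0 && finalRetention < 1,
            "finalRetention must be in (0, 1)")
  Ni <- if (schedule == "exponential") {
    pmax(ceiling(p * finalRetention^((seq_len(nRuns) - 1) / (nRuns - 1))), 1L)
  } else {
    pmax(ceiling(p * (1 - finalRetention)^(seq_len(nRuns) - 1)), 1L)
  }
  withSeed(stageSeed(seed, "cars"), {
    active <- seq_len(p)
    runSets <- vector("list", nRuns)
    rmse <- rep(NA_real_, nRuns)
    kept <- integer(nRuns)
    for (i in seq_len(nRuns)) {
      rows <- sort(sample.int(n, max(2L, floor(subsample * n))))
      fit <- tryCatch({
        nc <- min(plsComponents, length(active), length(rows) - 1L)
        fitPLSR(X[rows, active, drop = FALSE], yv[rows], nComponents = nc)
      }, error = function(e) NULL)
      if (is.null(fit)) { kept[i] <- length(active); runSets[[i]] <- active; next }
      w <- abs(fit@coefficients)
      keep <- min(Ni[i], length(active))
      topIdx <- active[order(-w)[seq_len(keep)]]
      wTop <- w[match(topIdx, active)]
      if (all(wTop == 0)) wTop <- rep(1, length(wTop))
      draws <- sample(seq_along(topIdx), size = keep, replace = TRUE,
                      prob = wTop / sum(wTop))
      active <- sort(unique(topIdx[draws]))
      kept[i] <- length(active)
      runSets[[i]] <- active
      rmse[i] <- tryCatch(
        .plsCvRmse(X, yv, active, min(plsComponents, length(active), n - 1L)),
        error = function(e) NA_real_)
    }
    if (all(is.na(rmse))) stop("all CARS runs failed", call. = FALSE)
    best <- which.min(rmse)
    idx <- as.integer(runSets[[best]])
    new("BandSelection", method = "cars", indices = idx,
        wavelengths = inp$wl[idx],
        diagnostics = list(
          pearson = .selectionDiagnostics(X, yv, idx, inp$wl),
          rmse = rmse, retained = kept, schedule = Ni, bestRun = best))
  })
}

# Cross-validated PLS RMSE on a fixed band subset.
.plsCvRmse <- function(X, y, idx, nComp, nFolds = 5L) {
  folds <- .interleavedFolds(length(y), nFolds)
  press <- 0
  for (f in seq_len(nFolds)) {
    tr <- folds != f
    nc <- min(nComp, sum(tr) - 1L, length(idx))
    fit <- fitPLSR(X[tr, idx, drop = FALSE], y[tr], nComponents = nc)
    pred <- predictPLSR(fit, X[!tr, idx, drop = FALSE])
    press <- press + sum((y[!tr] - pred)^2)
  }
  sqrt(press / length(y))
}

#' @rdname selectedBands
#' @export
setMethod("selectedBands", "BandSelection", function(x) x@indices)

setMethod("show", "BandSelection", function(object) {
  cat(sprintf("BandSelection [%s]: %d bands\n", object@method,
              length(object@indices)))
  if (length(object@indices))
    print(object@diagnostics$pearson, row.names = FALSE, digits = 3)
})

#' Export a band selection as CSV
#'
#' Columns wavelength (nm), Pearson r and |r| for the selected bands, with
#' the method recorded in a header comment.
#'
#' @param sel a [BandSelection-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeBandSelectionCSV <- function(sel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# method: %s", sel@method), con)
  utils::write.csv(
    data.frame(wavelength = sel@diagnostics$pearson$wavelength,
               r = sel@diagnostics$pearson$r,
               abs_r = sel@diagnostics$pearson$abs_r),
    con, row.names = FALSE)
  invisible(path)
}
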