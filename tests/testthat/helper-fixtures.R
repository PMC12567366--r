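# Shared fixtures: all synthetic, generated in code at test time.

# Reduced-size generator for fast unit tests (the acceptance tests use the
# full default 8 x 40 x 512 configuration).
smallConfig <- function(seed = 1, ...) {
  generatorConfig(nBands = 128L, replicates = 8L, seed = seed, ...)
}

fastCnn <- function(n, epochs = 30L, seed = 1L)
  cnnConfig(n, epochs = epochs, seed = seed)

# Independent SPA oracle: exhaustive starts; the projection chain is built
# with explicit least-squares residuals (qr), not the package's update
# formula; chains are scored by the same interleaved-fold OLS RMSE
# definition, re-implemented here.
oracleSpa <- function(X, y, nSelect, nFolds = 5L) {
  Xc <- sweep(X, 2L, colMeans(X))
  chainFrom <- function(start) {
    chain <- start
    for (s in seq_len(nSelect - 1L)) {
      B <- Xc[, chain, drop = FALSE]
      resid <- apply(Xc, 2L, function(col)
        sum(stats::lm.fit(B, col)$residuals^2))
      resid[chain] <- -1
      chain <- c(chain, which.max(resid))
    }
    chain
  }
  cvRmse <- function(idx) {
    folds <- rep_len(seq_len(nFolds), length(y))
    press <- 0
    for (f in seq_len(nFolds)) {
      tr <- folds != f
      d <- data.frame(y = y[tr], X[tr, idx, drop = FALSE])
      fit <- stats::lm(y ~ ., data = d)
      nd <- data.frame(X[!tr, idx, drop = FALSE])
      colnames(nd) <- colnames(d)[-1L]
      press <- press + sum((y[!tr] - stats::predict(fit, nd))^2)
    }
    sqrt(press / length(y))
  }
  chains <- lapply(seq_len(ncol(X)), chainFrom)
  scores <- vapply(chains, cvRmse, numeric(1))
  list(chain = chains[[which.min(scores)]], scores = scores)
}

# canonical row order used by the selectors, mirrored for the oracle
canonOrder <- function(X, y) do.call(order, c(list(y), list(X[, 1], X[, 2], X[, 3])))
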