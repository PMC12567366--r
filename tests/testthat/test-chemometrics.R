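test_that("PLS reduces to OLS in the exactly-solvable cases", {
  set.seed(1)
  # single predictor: coefficient equals the univariate OLS slope
  x <- matrix(rnorm(30), 30, 1)
  y <- 2.5 * x[, 1] + rnorm(30, sd = 0.2)
  m1 <- fitPLSR(x, y, nComponents = 1)
  expect_equal(m1@coefficients, unname(coef(lm(y ~ x))[2]), tolerance = 1e-10)
  # exact linear response along one of centred, mutually orthogonal
  # columns: a single component reproduces y
  X <- qr.Q(qr(scale(matrix(rnorm(80), 20, 4), scale = FALSE)))
  yl <- 3 * X[, 2]
  ml <- fitPLSR(X, yl, nComponents = 1)
  expect_equal(predictPLSR(ml, X), yl, tolerance = 1e-8)
  # full-rank PLS fitted values equal OLS fitted values
  yr <- rnorm(20)
  Xr <- matrix(rnorm(20 * 8), 20, 8)
  mf <- fitPLSR(Xr, yr, nComponents = 8)
  expect_equal(predictPLSR(mf, Xr), unname(fitted(lm(yr ~ Xr))),
               tolerance = 1e-8)
  # weight vectors are unit-norm
  expect_equal(unname(colSums(mf@weights^2)), rep(1, 8), tolerance = 1e-12)
  expect_error(fitPLSR(matrix(rnorm(20), 10, 2), rnorm(10), nComponents = 5),
               "collapse")
})

test_that("VIP normalization and planted-band argmax hold", {
  set.seed(2)
  X <- matrix(rnorm(200), 25, 8)
  y <- rnorm(25)
  m <- fitPLSR(X, y, nComponents = 4)
  v <- vipScores(m)
  expect_equal(mean(v^2), 1, tolerance = 1e-10)
  expect_equal(sum(v^2), 8, tolerance = 1e-10)
  # p = 1 forces VIP = 1
  m1 <- fitPLSR(matrix(rnorm(25), 25, 1), y, nComponents = 1)
  expect_equal(vipScores(m1), 1, tolerance = 1e-12)
  # synthetic standards: importance peaks at the planted 923 nm band
  cfg <- generatorConfig(seed = 15)
  std <- simulateStandardSeries(cfg)
  mp <- fitPLSR(std, nComponents = 5)
  expect_identical(which.max(vipScores(mp)), nearestBand(std, 923))
})

test_that("NMF is exact on rank-1 input and never increases its objective", {
  w <- runif(12, 0.5, 2)
  h <- runif(20, 0.1, 1)
  X1 <- outer(w, h)
  r1 <- nmfDecompose(X1, k = 1, maxIter = 2000, tol = 0, seed = 3)
  expect_lt(r1@errorTrace[length(r1@errorTrace)], 1e-8)
  set.seed(4)
  Xr <- matrix(runif(300, 0, 1), 15, 20)
  rr <- nmfDecompose(Xr, k = 3, maxIter = 200, seed = 5)
  expect_true(all(diff(rr@errorTrace) <= 1e-10))
  expect_true(all(rr@W >= 0) && all(rr@H >= 0))
  # seeded determinism
  rr2 <- nmfDecompose(Xr, k = 3, maxIter = 200, seed = 5)
  expect_identical(rr@H, rr2@H)
  expect_error(nmfDecompose(Xr - 10, k = 2), "negative")
})

test_that("NMF unmixing of synthetic leaves recovers the absorber component", {
  cfg <- generatorConfig(seed = 16)
  lvs <- simulateLeafSpectra(cfg)
  A <- toAbsorbance(lvs)
  res <- nmfDecompose(A, k = 2, maxIter = 400, seed = 6)
  eps <- absorberEpsilon(cfg)
  hit <- matchComponent(res, eps)
  expect_gte(hit$r, 0.95)
  # a reference equal to a component row matches itself with r = 1
  self <- matchComponent(res, res@H[1, ])
  expect_identical(self$component, 1L)
  expect_equal(self$r, 1, tolerance = 1e-12)
})

test_that("PCA variance fractions, orthogonality and sign convention hold", {
  set.seed(5)
  X <- matrix(rnorm(180), 30, 6)
  p <- pcaSpectra(X)
  expect_equal(sum(p@varianceFraction), 1, tolerance = 1e-10)
  expect_true(all(diff(p@varianceFraction) <= 1e-12))
  G <- crossprod(p@scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  expect_equal(crossprod(p@rotation), diag(6), tolerance = 1e-10,
               ignore_attr = TRUE)
  # largest-magnitude loading positive in every component
  for (j in 1:6) {
    l <- p@rotation[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
  # a 2-D point cloud on a line: one component explains everything
  t <- rnorm(40)
  line <- cbind(2 * t + 1, -3 * t + 2)
  pl <- pcaSpectra(line, nComponents = 1)
  expect_equal(pl@varianceFraction[1], 1, tolerance = 1e-10)
  expect_error(pcaSpectra(matrix(1, 5, 3)), "variance")
  expect_error(pcaSpectra(X, nComponents = 10), "rank")
})

test_that("regression metrics satisfy their defining identities", {
  y <- c(1, 2, 3, 4, 5)
  perfect <- regressionMetrics(y, y)
  expect_equal(perfect@r2, 1)
  expect_equal(perfect@rmse, 0)
  expect_identical(perfect@rpd, Inf)
  constant <- regressionMetrics(y, rep(mean(y), 5))
  expect_equal(constant@r2, 0)
  expect_equal(constant@rpd, 1, tolerance = 1e-12)
  # population-SD convention: RPD = (1 - R2)^(-1/2) exactly
  set.seed(6)
  for (i in 1:20) {
    yt <- rnorm(15)
    yp <- yt + rnorm(15, sd = runif(1, 0.1, 2))
    m <- regressionMetrics(yt, yp)
    expect_equal(m@rpd, (1 - m@r2)^(-0.5), tolerance = 1e-12)
  }
  # sample-SD variant differs by sqrt(n/(n-1))
  ms <- regressionMetrics(y, y + 0.5, sdType = "sample")
  mp <- regressionMetrics(y, y + 0.5)
  expect_equal(ms@rpd / mp@rpd, sqrt(5 / 4), tolerance = 1e-12)
  expect_error(regressionMetrics(rep(1, 4), rnorm(4)), "variance")
})

test_that("rank-method AUC matches pair counting and an external oracle", {
  rc <- rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(rc$auc, 0.75)  # wins 3 of the 4 positive-negative pairs
  expect_equal(rocAuc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(rocAuc(1:4, rep(1, 4)), "both classes")
  # ROC points: monotone staircase from (0,0) to (1,1)
  set.seed(7)
  s <- rnorm(40)
  l <- as.integer(s + rnorm(40, sd = 0.8) > 0)
  rc2 <- rocAuc(s, l)
  expect_true(all(diff(rc2$points$fpr) >= 0))
  expect_true(all(diff(rc2$points$tpr) >= 0))
  expect_equal(unlist(rc2$points[nrow(rc2$points), c("fpr", "tpr")]),
               c(fpr = 1, tpr = 1))
  skip_if_not_installed("pROC")
  oracle <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                           direction = "<")))
  expect_equal(rc2$auc, oracle, tolerance = 1e-12)
})

test_that("full-rank PLS matches an external PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(8)
  X <- matrix(rnorm(25 * 6), 25, 6)
  colnames(X) <- paste0("b", 1:6)
  y <- rnorm(25)
  ours <- fitPLSR(X, y, nComponents = 3)
  theirs <- mixOmics::pls(X, y, ncomp = 3, scale = FALSE, mode = "regression")
  pred <- predict(theirs, X)$predict[, 1, 3]
  ourPred <- drop(cbind(1, X) %*% c(ours@intercept, ours@coefficients))
  expect_equal(unname(ourPred), unname(pred), tolerance = 1e-6)
})
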