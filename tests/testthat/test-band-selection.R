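test_that("pearsonTable agrees with a definitionally independent oracle", {
  set.seed(7)
  X <- matrix(rnorm(100), 20, 5)
  y <- rnorm(20)
  tab <- pearsonTable(X, y)
  oracle <- vapply(1:5, function(j) {
    cov(X[, j], y) / (sd(X[, j]) * sd(y))
  }, numeric(1))
  expect_equal(tab$r, oracle, tolerance = 1e-12)
  # perfect and anti-perfect bands
  X2 <- cbind(y, -y, rnorm(20))
  t2 <- pearsonTable(X2, y)
  expect_equal(t2$r[1:2], c(1, -1), tolerance = 1e-12)
  # zero-variance band flagged with r = 0
  X3 <- cbind(rep(1, 20), y)
  t3 <- pearsonTable(X3, y)
  expect_true(t3$flagged[1])
  expect_equal(t3$r[1], 0)
  expect_error(pearsonTable(X, rep(1, 20)), "variance")
})

test_that("pearson filter honours the threshold and |r| ordering", {
  set.seed(8)
  y <- rnorm(30)
  X <- cbind(y + rnorm(30, sd = 0.1), rnorm(30), y + rnorm(30, sd = 0.5))
  selAll <- pearsonSelect(X, y, threshold = 0)
  expect_setequal(selAll@indices, 1:3)
  expect_true(all(diff(selAll@diagnostics$pearson$abs_r) <= 0))
  selNone <- pearsonSelect(X, y, threshold = 1)
  expect_length(selNone@indices, 0)
  # planted-band recovery on the synthetic series
  cfg <- smallConfig(seed = 9)
  std <- simulateStandardSeries(cfg)
  sel <- pearsonSelect(std)
  expect_true(nearestBand(std, 923) %in% sel@indices)
})

test_that("SPA equals the exhaustive-start oracle on a small instance", {
  set.seed(21)
  n <- 24
  X <- matrix(rnorm(n * 6), n, 6)
  X[, 4] <- X[, 1] * 0.6 + rnorm(n, sd = 0.2)
  y <- 2 * X[, 2] - X[, 5] + rnorm(n, sd = 0.3)
  ord <- canonOrder(X, y)
  oracle <- oracleSpa(X[ord, ], y[ord], nSelect = 3)
  sel <- spaSelect(X, y, nSelect = 3)
  expect_identical(sel@indices, as.integer(oracle$chain))
  expect_equal(unname(sel@diagnostics$scores), unname(oracle$scores),
               tolerance = 1e-8)
})

test_that("SPA selections are non-collinear with positive projection norms", {
  cfg <- smallConfig(seed = 10)
  std <- simulateStandardSeries(cfg)
  sel <- spaSelect(std, nSelect = 8)
  expect_length(unique(sel@indices), 8)
  G <- crossprod(scale(spectra(std)[, sel@indices], scale = FALSE))
  expect_equal(qr(G)$rank, 8)
  expect_true(all(sel@diagnostics$projectionNorms > 0))
  # single-band request reduces to the best one-variable fit
  sel1 <- spaSelect(std, nSelect = 1)
  expect_length(sel1@indices, 1)
  # impossible chains fail loudly
  Xr <- cbind(1:9, (1:9) * 2, (1:9) * 3)
  expect_error(spaSelect(Xr + 0, (1:9) + 0, nSelect = 3), "rank|achievable")
})

test_that("CARS follows its schedule and recovers a planted band", {
  # schedule endpoints: N_1 = p, N_last = ceiling(0.1 * p)
  set.seed(30)
  X5 <- matrix(rnorm(100), 20, 5)
  y5 <- rnorm(20)
  s2 <- carsSelect(X5, y5, nRuns = 2, plsComponents = 2, seed = 4)
  expect_equal(s2@diagnostics$schedule, c(5, 1))
  # planted informative band among pure noise bands
  set.seed(31)
  n <- 60
  informative <- rnorm(n)
  X <- cbind(matrix(rnorm(n * 9, sd = 1), n, 9), informative)
  y <- 3 * informative + rnorm(n, sd = 0.2)
  sel <- carsSelect(X, y, nRuns = 12, plsComponents = 3, seed = 5)
  expect_true(10 %in% sel@indices)
  expect_lt(length(sel@indices), ncol(X))
  # monotone active-set size and the final-retention bound
  expect_true(all(diff(sel@diagnostics$retained) <= 0))
  expect_lte(sel@diagnostics$retained[12], ceiling(0.1 * ncol(X)))
  # seeded determinism of the full trace
  sel2 <- carsSelect(X, y, nRuns = 12, plsComponents = 3, seed = 5)
  expect_identical(sel@indices, sel2@indices)
  expect_identical(sel@diagnostics$rmse, sel2@diagnostics$rmse)
})

test_that("selectors are invariant to row permutation", {
  cfg <- smallConfig(seed = 13)
  std <- simulateStandardSeries(cfg)
  set.seed(99)
  perm <- sample(nrow(spectra(std)))
  std2 <- spectraTable(spectra(std)[perm, ], generatorGrid(cfg),
                       groupLabels(std)[perm], concentrations(std)[perm])
  expect_identical(pearsonSelect(std)@indices, pearsonSelect(std2)@indices)
  expect_identical(spaSelect(std, nSelect = 5)@indices,
                   spaSelect(std2, nSelect = 5)@indices)
  expect_identical(carsSelect(std, nRuns = 8, seed = 3)@indices,
                   carsSelect(std2, nRuns = 8, seed = 3)@indices)
})

test_that("selection tables export in the tabulated wavelength/r format", {
  cfg <- smallConfig(seed = 14)
  std <- simulateStandardSeries(cfg)
  sel <- spaSelect(std, nSelect = 5)
  p <- withr::local_tempfile(fileext = ".csv")
  writeBandSelectionCSV(sel, p)
  expect_match(readLines(p, n = 1), "# method: spa")
  df <- read.csv(p, comment.char = "#")
  expect_named(df, c("wavelength", "r", "abs_r"))
  expect_equal(df$abs_r, abs(df$r), tolerance = 1e-12)
  expect_equal(df$wavelength, sel@wavelengths, tolerance = 1e-6)
})
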