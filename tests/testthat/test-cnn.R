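test_that("architecture dimensioning follows the closed forms", {
  cfg <- cnnConfig(10)
  d <- cnnDimensions(cfg)
  expect_equal(d$convLen, 6L)   # 10 - 5 + 1
  expect_equal(d$poolLen, 3L)   # floor(6/2)
  expect_equal(d$flatLen, 192L) # 3 * 64
  expect_identical(cnnParameterCount(cfg), 6593L)  # 384 + 6176 + 33
  # actual parameter vectors agree with the formula
  m <- trainCNN(matrix(rnorm(200), 20, 10), rnorm(20),
                cnnConfig(10, epochs = 1))
  expect_identical(sum(lengths(m@params)), 6593L)
  # boundary: 5 input bands give conv length 1, pooled length 0 -> rejected
  expect_error(cnnConfig(5), "pooled length")
  expect_error(cnnConfig(3, kernel = 5), "kernel")
})

test_that("training is bit-reproducible and prediction is a pure function", {
  set.seed(9)
  X <- matrix(rnorm(300), 30, 10)
  y <- X[, 3] * 5 + rnorm(30, sd = 0.1)
  m1 <- trainCNN(X, y, cnnConfig(10, epochs = 10, seed = 7))
  m2 <- trainCNN(X, y, cnnConfig(10, epochs = 10, seed = 7))
  expect_identical(m1@params, m2@params)
  expect_identical(m1@lossTrace, m2@lossTrace)
  p1 <- predict(m1, X)
  expect_identical(as.numeric(p1), as.numeric(predict(m1, X)))
  expect_error(predict(m1, X[, 1:7]), "mismatch")
})

test_that("standardization state comes from training rows only (no leakage)", {
  set.seed(10)
  X <- matrix(rnorm(400), 40, 10)
  y <- rowSums(X[, 1:2]) + rnorm(40, sd = 0.1)
  tr <- 1:30
  m <- trainCNN(X[tr, ], y[tr], cnnConfig(10, epochs = 5, seed = 1))
  expect_equal(m@xCenter, colMeans(X[tr, ]), tolerance = 1e-12)
  expect_equal(m@xScale, apply(X[tr, ], 2, sd), tolerance = 1e-12)
  # retraining with different "future" rows appended changes nothing
  m2 <- trainCNN(X[tr, ], y[tr], cnnConfig(10, epochs = 5, seed = 1))
  expect_identical(m@params, m2@params)
})

test_that("cross-validation is stratified, seeded and leak-free", {
  cfg <- smallConfig(seed = 17)
  std <- simulateStandardSeries(cfg)
  sel <- spaSelect(std, nSelect = 8)
  cv1 <- cnnCrossValidate(std, k = 4, bands = sel,
                          config = fastCnn(8, epochs = 8), seed = 2)
  # every fold contains every concentration group
  for (f in 1:4)
    expect_setequal(unique(groupLabels(std)[cv1$folds == f]),
                    unique(groupLabels(std)))
  cv2 <- cnnCrossValidate(std, k = 4, bands = sel,
                          config = fastCnn(8, epochs = 8), seed = 2)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$metrics@rmse, cv2$metrics@rmse)
  # permuting rows inside the held-out fold cannot change training
  expect_error(cnnCrossValidate(spectra(std)[1:5, 1:8], rnorm(5), k = 4),
               "stratification")
})

test_that("the regressor learns a noiseless band-selected series", {
  # a noiseless table has only as many distinct rows as groups, so the
  # bands are chosen on its noisy twin and the network is evaluated on the
  # noise-free target
  sel <- spaSelect(simulateStandardSeries(smallConfig(seed = 18)),
                   nSelect = 8)
  cfg0 <- smallConfig(seed = 18, noiseSD = 0, jitterSD = 0)
  std0 <- simulateStandardSeries(cfg0)
  cv <- cnnCrossValidate(std0, k = 4, bands = sel,
                         config = fastCnn(8, epochs = 60), seed = 3)
  expect_gte(cv$metrics@r2, 0.95)
  # constant target: metrics flag the undefined R2
  expect_error(regressionMetrics(rep(5, 10), rnorm(10)), "variance")
})

test_that("extrapolation beyond the training range is flagged", {
  set.seed(11)
  X <- matrix(rnorm(300), 30, 10)
  y <- seq(0, 1000, length.out = 30)
  m <- trainCNN(X, y, cnnConfig(10, epochs = 3, seed = 2))
  shifted <- X + 5
  p <- predict(m, rbind(X, shifted))
  flags <- attr(p, "extrapolated")
  expect_identical(flags, p < 0 | p > 1000)
})

test_that("models reload from the plain-text directory bit-reproducibly", {
  set.seed(12)
  X <- matrix(rnorm(200), 20, 10)
  y <- rnorm(20) * 100 + 500
  m <- trainCNN(X, y, cnnConfig(10, epochs = 5, seed = 4),
                bandIndices = 1:10, bandWavelengths = 901:910)
  dir <- withr::local_tempdir()
  saveCNN(m, dir)
  expect_true(file.exists(file.path(dir, "params.json")))
  expect_true(file.exists(file.path(dir, "model_info.txt")))
  m2 <- loadCNN(dir)
  expect_equal(m2@params, m@params, tolerance = 1e-15)
  expect_identical(as.numeric(predict(m2, X)), as.numeric(predict(m, X)))
  expect_identical(m2@bandIndices, m@bandIndices)
})
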