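mkTable <- function(X, domain = "reflectance", conc = NULL, labels = NULL) {
  g <- makeWavelengthGrid(ncol(X), 900, 1700)
  spectraTable(X, g, labels = labels %||% as.character(seq_len(nrow(X))),
               concentration = conc %||% numeric(0), domain = domain)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("absorbance transform and its inverse agree", {
  X <- rbind(c(1, 0.1, 0.5, 0.25), c(0.9, 0.01, 0.33, 1))
  tab <- toAbsorbance(mkTable(X))
  expect_equal(spectra(tab)[1, ], c(0, 1, 0.30103, 0.60206),
               tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(10^(-spectra(tab)), X, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(toAbsorbance(tab), "reflectance")
})

test_that("net absorbance zeroes the blank and is idempotent at zero noise", {
  cfg <- smallConfig(seed = 6, noiseSD = 0, jitterSD = 0)
  std <- simulateStandardSeries(cfg)
  net <- netAbsorbance(toAbsorbance(std))
  blankRows <- spectra(net)[groupLabels(net) == "0", ]
  expect_equal(max(abs(blankRows)), 0, tolerance = 1e-12)
  # subtracting the blank again changes nothing at zero noise
  net2 <- netAbsorbance(net)
  expect_equal(spectra(net2), spectra(net), tolerance = 1e-12)
  # planted-band net signal equals the saturated response exactly where the
  # broadband suppression is off (c * peak below the knee)
  b <- nearestBand(std, 923)
  eps923 <- absorberEpsilon(cfg)[b]
  m200 <- colMeans(spectra(net)[groupLabels(net) == "200", ])[b]
  expect_equal(m200, saturationResponse(cfg, 200 * eps923), tolerance = 1e-12)
  expect_error(netAbsorbance(toAbsorbance(std), "nope"), "blank")
})

test_that("Savitzky-Golay derivatives reproduce polynomial rows", {
  n <- 64
  idx <- seq_len(n)
  const <- rep(2.5, n)
  ramp <- 0.03 * idx
  quad <- 0.002 * idx^2 - 0.1 * idx + 4
  tab <- mkTable(rbind(const, ramp, quad))
  d1 <- spectra(spectralDerivative(tab, 1, window = 11, polyorder = 2))
  inner <- 6:(n - 6)
  expect_equal(max(abs(d1[1, inner])), 0, tolerance = 1e-10)
  expect_equal(d1[2, inner], rep(0.03, length(inner)), tolerance = 1e-10,
               ignore_attr = TRUE)
  d2 <- spectra(spectralDerivative(tab, 2, window = 11, polyorder = 3))
  expect_equal(d2[3, inner], rep(2 * 0.002, length(inner)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(spectralDerivative(tab, 1, window = 10), "odd")
  expect_error(spectralDerivative(tab, 2, window = 11, polyorder = 1),
               "polyorder")
})

test_that("SNV rows have mean 0 and SD 1; MSC inverts affine scatter", {
  set.seed(42)
  X <- matrix(runif(300, 0.2, 0.9), 10, 30)
  s <- snv(mkTable(X))
  expect_equal(unname(rowMeans(spectra(s))), rep(0, 10), tolerance = 1e-10)
  expect_equal(unname(apply(spectra(s), 1, sd)), rep(1, 10), tolerance = 1e-10)
  expect_error(snv(mkTable(rbind(rep(1, 5), runif(5)))), "zero-variance")

  ref <- colMeans(X)
  m <- msc(mkTable(rbind(ref, 2 + 3 * ref)), reference = ref)
  expect_equal(spectra(m)[1, ], ref, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(spectra(m)[2, ], ref, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("group statistics match hand-computed values and scale invariance", {
  X <- rbind(c(0.4, 0.4), c(0.6, 0.6), c(0.5, 0.1), c(0.5, 0.3))
  tab <- mkTable(X, labels = c("a", "a", "b", "b"))
  gs <- groupStats(tab)
  expect_equal(unname(gs@mean["a", 1]), 0.5)
  expect_equal(unname(gs@sd["a", 1]), 0.1414214, tolerance = 1e-6)
  expect_equal(unname(gs@cv["a", 1]), 28.28427, tolerance = 1e-4)
  # identical rows: SD = CV = 0
  same <- groupStats(mkTable(rbind(c(0.3, 0.4), c(0.3, 0.4)),
                             labels = c("g", "g")))
  expect_equal(unname(same@sd["g", ]), c(0, 0))
  expect_equal(unname(same@cv["g", ]), c(0, 0))
  # CV unchanged under uniform scaling of a group's rows
  gs2 <- groupStats(mkTable(X * 7, labels = c("a", "a", "b", "b")))
  expect_equal(gs2@cv, gs@cv, tolerance = 1e-10)
  expect_error(groupStats(mkTable(X, labels = c("a", "a", "b", "c"))),
               "singleton")
})

test_that("spectra tables survive the CSV interchange format", {
  cfg <- smallConfig(seed = 8)
  std <- simulateStandardSeries(cfg)
  p <- withr::local_tempfile(fileext = ".csv")
  writeSpectraCSV(std, p)
  back <- readSpectraCSV(p)
  expect_equal(spectra(back), spectra(std), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(groupLabels(back), groupLabels(std))
  expect_equal(concentrations(back), concentrations(std))
  expect_identical(spectralDomain(back), "reflectance")
  # wavelengths are written with one decimal by the interchange format
  expect_equal(wavelengths(back), wavelengths(std), tolerance = 1e-3)
})
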