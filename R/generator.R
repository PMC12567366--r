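#' Synthetic NIR spectra generator configuration
#'
#' Builds a [GeneratorConfig-class] whose defaults emulate the study
#' conditions the package is designed around: an 8-level dilution series of
#' a pure absorber (0, 0.32, 1.6, 8, 40, 200, 800, 1000 ug/mL) with 40
#' replicate spectra per group on a 512-band 900--1700 nm grid, plus eight
#' leaf "cultivars" carrying the same absorber at cultivar-specific
#' effective loadings inside a leaf matrix (water band near 1450 nm and a
#' gentle structural slope).
#'
#' The spectral model works in absorbance.  For a standard at concentration
#' `c`:
#' \deqn{A(\lambda) = B(\lambda) + sat(c\,\epsilon(\lambda)) +
#'       \gamma \max(0, c\,\epsilon_{max} - K)\, z(\lambda)}
#' where `B` is a polynomial baseline, `eps` the absorber profile (a
#' Gaussian at the primary band plus an optional minor band), `sat` a
#' soft-clip response that is linear below the knee `K` and saturating
#' above it, and `z` a long-wavelength sigmoid carrying the broadband
#' reflectance suppression seen once the primary band saturates.  Replicates
#' get a scalar absorbance baseline jitter; reflectance `R = 10^(-A)` then
#' receives independent Gaussian noise per band and is clipped below at a
#' positive floor.
#'
#' The primary absorber centre defaults to the grid wavelength nearest
#' 923 nm, so band-recovery checks against `nearestBand(grid, 923)` are
#' well-posed.
#'
#' @param nBands,loWavelength,hiWavelength grid specification.
#' @param concentrations dilution series (ug/mL).
#' @param replicates replicate spectra per group (>= 2).
#' @param absorberCenter primary band centre (nm); `NULL` snaps 923 nm to
#'   the grid.
#' @param absorberSigma,absorberAmplitude Gaussian width (nm) and absorbance
#'   per (ug/mL) of the primary band.
#' @param minorCenter,minorSigma,minorAmplitude secondary absorber band.
#' @param baselineCoef baseline polynomial coefficients in
#'   `u = (lambda - 1300)/400`.
#' @param saturationKnee,saturationHeadroom soft-clip knee and residual
#'   headroom (AU).
#' @param suppressionGamma,suppressionCenter,suppressionWidth broadband
#'   suppression strength and sigmoid shape.
#' @param leafBase,leafSlope,waterAmplitude,waterCenter,waterSigma leaf
#'   matrix absorbance components.
#' @param cultivarLoadings named numeric vector of effective absorber
#'   concentrations (ug/mL) per cultivar.
#' @param noiseSD reflectance noise sd; `jitterSD` absorbance jitter sd.
#' @param reflectanceFloor positive clip floor.
#' @param seed integer master seed.  Stages draw from derived streams in a
#'   fixed order: standards = seed, leaves = seed + 1, cube = seed + 2.
#' @return a validated [GeneratorConfig-class].
#' @examples
#' cfg <- generatorConfig(seed = 1)
#' std <- simulateStandardSeries(cfg)
#' std
#' @export
generatorConfig <- function(nBands = 512L, loWavelength = 900,
    hiWavelength = 1700,
    concentrations = c(0, 0.32, 1.6, 8, 40, 200, 800, 1000),
    replicates = 40L,
    absorberCenter = NULL, absorberSigma = 9, absorberAmplitude = 5.5e-4,
    minorCenter = 1135, minorSigma = 25, minorAmplitude = 1.2e-4,
    baselineCoef = c(0.18, 0.04, 0.02),
    saturationKnee = 0.45, saturationHeadroom = 0.10,
    suppressionGamma = 35, suppressionCenter = 1520, suppressionWidth = 60,
    leafBase = 0.16, leafSlope = 0.005,
    waterAmplitude = 0.03, waterCenter = 1450, waterSigma = 40,
    cultivarLoadings = NULL,
    noiseSD = 0.004, jitterSD = 0.005,
    reflectanceFloor = 1e-6, seed = 1L) {
  grid <- makeWavelengthGrid(nBands, loWavelength, hiWavelength)
  if (is.null(absorberCenter))
    absorberCenter <- wavelengths(grid)[nearestBand(grid, 923)]
  if (is.null(cultivarLoadings)) {
    cultivarLoadings <- c(150, 220, 320, 450, 640, 900, 1150, 1450)
    names(cultivarLoadings) <- sprintf("cultivar%02d", seq_along(cultivarLoadings))
  }
  new("GeneratorConfig", nBands = as.integer(nBands),
      loWavelength = loWavelength, hiWavelength = hiWavelength,
      concentrations = concentrations, replicates = as.integer(replicates),
      absorberCenter = absorberCenter, absorberSigma = absorberSigma,
      absorberAmplitude = absorberAmplitude,
      minorCenter = minorCenter, minorSigma = minorSigma,
      minorAmplitude = minorAmplitude,
      baselineCoef = baselineCoef,
      saturationKnee = saturationKnee, saturationHeadroom = saturationHeadroom,
      suppressionGamma = suppressionGamma,
      suppressionCenter = suppressionCenter, suppressionWidth = suppressionWidth,
      leafBase = leafBase, leafSlope = leafSlope,
      waterAmplitude = waterAmplitude, waterCenter = waterCenter,
      waterSigma = waterSigma,
      cultivarLoadings = cultivarLoadings,
      noiseSD = noiseSD, jitterSD = jitterSD,
      reflectanceFloor = reflectanceFloor, seed = as.integer(seed))
}

#' Wavelength grid of a generator configuration
#' @param config a [GeneratorConfig-class].
#' @return the [WavelengthGrid-class] the generator emits.
#' @export
generatorGrid <- function(config)
  makeWavelengthGrid(config@nBands, config@loWavelength, config@hiWavelength)

#' Generator truth functions
#'
#' Noise-free components of the synthetic spectral model, exposed so tests
#' and diagnostics can compare fitted results against the planted truth.
#'
#' `absorberEpsilon` is the molar-absorptivity-like profile (AU per ug/mL);
#' it is non-negative everywhere.  `standardAbsorbance` evaluates the full
#' noise-free standard absorbance for each concentration;
#' `leafMatrixAbsorbance` the cultivar-independent leaf matrix; and
#' `saturationResponse` the soft-clip response applied to the absorber term.
#'
#' @param config a [GeneratorConfig-class].
#' @param concentration numeric vector of concentrations (ug/mL).
#' @param a absorbance before the saturation response.
#' @return `absorberEpsilon` and `leafMatrixAbsorbance`: numeric vectors of
#'   length `nBands`; `standardAbsorbance`: matrix bands x concentrations;
#'   `saturationResponse`: numeric like `a`.
#' @export
absorberEpsilon <- function(config) {
  lam <- wavelengths(generatorGrid(config))
  config@absorberAmplitude *
    exp(-(lam - config@absorberCenter)^2 / (2 * config@absorberSigma^2)) +
  config@minorAmplitude *
    exp(-(lam - config@minorCenter)^2 / (2 * config@minorSigma^2))
}

#' @rdname absorberEpsilon
#' @export
saturationResponse <- function(config, a) {
  k <- config@saturationKnee
  h <- config@saturationHeadroom
  ifelse(a <= k, a, k + h * tanh((a - k) / h))
}

#' @rdname absorberEpsilon
#' @export
standardAbsorbance <- function(config, concentration = config@concentrations) {
  lam <- wavelengths(generatorGrid(config))
  u <- (lam - 1300) / 400
  baseline <- drop(outer(u, seq_along(config@baselineCoef) - 1, `^`) %*%
                     config@baselineCoef)
  eps <- absorberEpsilon(config)
  z <- 1 / (1 + exp(-(lam - config@suppressionCenter) / config@suppressionWidth))
  peak <- config@absorberAmplitude
  vapply(concentration, function(cc) {
    baseline + saturationResponse(config, cc * eps) +
      config@suppressionGamma * max(0, cc * peak - config@saturationKnee) * z
  }, numeric(length(lam)))
}

#' @rdname absorberEpsilon
#' @export
leafMatrixAbsorbance <- function(config) {
  lam <- wavelengths(generatorGrid(config))
  x <- (lam - config@loWavelength) / (config@hiWavelength - config@loWavelength)
  config@leafBase + config@leafSlope * x +
    config@waterAmplitude *
      exp(-(lam - config@waterCenter)^2 / (2 * config@waterSigma^2))
}

# absorbance -> noisy reflectance rows; one row per (column of A, replicate)
.absorbanceToNoisyRows <- function(A, nrep, noiseSD, jitterSD, floor) {
  nb <- nrow(A); ng <- ncol(A)
  out <- matrix(0, nrow = ng * nrep, ncol = nb)
  k <- 0L
  for (j in seq_len(ng)) {
    for (i in seq_len(nrep)) {
      k <- k + 1L
      jit <- if (jitterSD > 0) stats::rnorm(1L, 0, jitterSD) else 0
      r <- 10^(-(A[, j] + jit))
      if (noiseSD > 0) r <- r + stats::rnorm(nb, 0, noiseSD)
      out[k, ] <- pmax(r, floor)
    }
  }
  out
}

#' Simulate the standard dilution series
#'
#' Draws `replicates` noisy reflectance spectra for every concentration of
#' the dilution series from the generator's spectral model.  Output is
#' deterministic in `(config, seed)`: the standards stage uses the seed
#' stream `config@seed`.
#'
#' @param config a [GeneratorConfig-class].
#' @return a concentration-labelled reflectance [SpectraTable-class] with
#'   `length(concentrations) * replicates` rows.
#' @export
simulateStandardSeries <- function(config) {
  validObject(config)
  A <- standardAbsorbance(config)
  X <- withSeed(stageSeed(config@seed, "standards"),
    .absorbanceToNoisyRows(A, config@replicates, config@noiseSD,
                           config@jitterSD, config@reflectanceFloor))
  conc <- rep(config@concentrations, each = config@replicates)
  spectraTable(X, generatorGrid(config),
               labels = as.character(conc),
               concentration = conc, domain = "reflectance")
}

#' Simulate leaf spectra for each cultivar
#'
#' Per cultivar, replicate absorbance spectra are the shared leaf matrix
#' plus `loading * absorberEpsilon(config)`, mapped to noisy reflectance
#' exactly as for the standards.  The loadings used are recorded in the
#' configuration (`config@cultivarLoadings`), which is the ground truth for
#' transfer experiments.  Uses seed stream `config@seed + 1`.
#'
#' @param config a [GeneratorConfig-class] with at least two cultivars.
#' @return a cultivar-labelled reflectance [SpectraTable-class].
#' @export
simulateLeafSpectra <- function(config) {
  validObject(config)
  loads <- config@cultivarLoadings
  stopIfNot(length(loads) >= 2L, "need at least 2 cultivars")
  matx <- leafMatrixAbsorbance(config)
  eps <- absorberEpsilon(config)
  A <- vapply(loads, function(L) matx + L * eps, numeric(length(matx)))
  X <- withSeed(stageSeed(config@seed, "leaves"),
    .absorbanceToNoisyRows(A, config@replicates, config@noiseSD,
                           config@jitterSD, config@reflectanceFloor))
  spectraTable(X, generatorGrid(config),
               labels = rep(names(loads), each = config@replicates),
               domain = "reflectance")
}

#' Scene layout for raw-cube simulation
#'
#' `sceneSpec` describes a flat background with rectangular sample patches;
#' each patch has a true reflectance, either a scalar (spectrally flat) or a
#' per-band vector.
#'
#' @param lines,samples spatial dimensions of the cube.
#' @param background background true reflectance (scalar or per-band).
#' @param patches list of `scenePatch` objects.
#' @param rows,cols integer ranges covered by a patch.
#' @param reflectance patch true reflectance (scalar or per-band vector).
#' @return `sceneSpec`: a list with class `"sceneSpec"`; `scenePatch`: a
#'   list with class `"scenePatch"`.
#' @export
sceneSpec <- function(lines, samples, background = 0, patches = list()) {
  stopIfNot(length(patches) >= 1L, "scene needs at least one patch")
  structure(list(lines = as.integer(lines), samples = as.integer(samples),
                 background = background, patches = patches),
            class = "sceneSpec")
}

#' @rdname sceneSpec
#' @export
scenePatch <- function(rows, cols, reflectance) {
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 reflectance = reflectance), class = "scenePatch")
}

#' Simulate a raw / dark / white cube triple
#'
#' Emulates acquisition of a scene under a flat-field illumination: the
#' white reference cube is a constant high digital-number level, the dark
#' cube a small positive offset, and the raw cube
#' `dark + (white - dark) * R_true` plus optional noise (sd
#' `noiseSD * (white - dark)` digital numbers).  Radiometric correction of
#' the triple recovers the scene's true reflectance exactly at zero noise.
#' Uses seed stream `config@seed + 2`.
#'
#' @param config a [GeneratorConfig-class] (supplies grid, noise and seed).
#' @param scene a [sceneSpec()] layout.
#' @param whiteLevel,darkLevel digital-number levels of the references.
#' @return list with elements `raw`, `dark`, `white` (raw-kind
#'   [HyperCube-class]s) and `truth` (the true reflectance array).
#' @export
simulateRawCube <- function(config, scene, whiteLevel = 3500, darkLevel = 80) {
  stopIfNot(inherits(scene, "sceneSpec"), "scene must be a sceneSpec()")
  grid <- generatorGrid(config)
  nb <- nBands(grid)
  dims <- c(scene$lines, scene$samples, nb)
  truth <- array(0, dims)
  bg <- scene$background
  truth[] <- rep(if (length(bg) == 1L) rep(bg, nb) else bg, each = prod(dims[1:2]))
  for (p in scene$patches) {
    stopIfNot(all(p$rows >= 1L) && all(p$rows <= scene$lines) &&
              all(p$cols >= 1L) && all(p$cols <= scene$samples),
              "patch outside cube bounds")
    refl <- if (length(p$reflectance) == 1L) rep(p$reflectance, nb) else p$reflectance
    stopIfNot(length(refl) == nb, "patch reflectance must be scalar or per-band")
    for (b in seq_len(nb)) truth[p$rows, p$cols, b] <- refl[b]
  }
  white <- array(whiteLevel, dims)
  dark <- array(darkLevel, dims)
  raw <- dark + (white - dark) * truth
  sdDN <- config@noiseSD * (whiteLevel - darkLevel)
  if (sdDN > 0) {
    noise <- withSeed(stageSeed(config@seed, "cube"), list(
      raw = array(stats::rnorm(prod(dims), 0, sdDN), dims),
      dark = array(stats::rnorm(prod(dims), 0, sdDN / 4), dims)))
    raw <- raw + noise$raw
    dark <- dark + noise$dark
  }
  list(raw = new("HyperCube", data = raw, grid = grid, kind = "raw"),
       dark = new("HyperCube", data = dark, grid = grid, kind = "raw"),
       white = new("HyperCube", data = white, grid = grid, kind = "raw"),
       truth = truth)
}
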