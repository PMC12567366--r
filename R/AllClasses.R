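#' @import methods
NULL

#' Wavelength grid of a hyperspectral sensor
#'
#' A strictly increasing vector of band-centre wavelengths in nanometres.
#' All spectra and cubes in the package carry one of these so that band
#' indices can always be resolved back to physical wavelengths.
#'
#' @slot values numeric vector of wavelengths (nm), strictly increasing.
#' @seealso [makeWavelengthGrid()], [nearestBand()]
#' @export
setClass("WavelengthGrid", representation(values = "numeric"))

setValidity("WavelengthGrid", function(object) {
  v <- object@values
  if (length(v) < 2L) return("a wavelength grid needs at least 2 bands")
  if (any(!is.finite(v))) return("wavelengths must be finite")
  if (any(diff(v) <= 0)) return("wavelengths must be strictly increasing")
  TRUE
})

#' Table of replicate spectra with group labels
#'
#' The workhorse container for chemometric analysis: one row per replicate
#' spectrum, one column per band.  Rows carry a group label (a concentration
#' group of the dilution series, or a cultivar name) and, optionally, a
#' numeric concentration in ug/mL.  The `domain` tag records which spectral
#' domain the values live in, so transforms can refuse nonsense input.
#'
#' @slot spectra numeric matrix, rows = replicate spectra, cols = bands.
#' @slot grid the [WavelengthGrid-class] shared by all rows.
#' @slot labels character vector of per-row group labels.
#' @slot concentration numeric per-row concentration (ug/mL); length zero
#'   when the table is labelled by cultivar rather than concentration.
#' @slot domain one of `"reflectance"`, `"absorbance"`, `"net_absorbance"`,
#'   `"derivative_1"`, `"derivative_2"`, `"snv"`, `"msc"`.
#' @export
setClass("SpectraTable",
  representation(spectra = "matrix", grid = "WavelengthGrid",
                 labels = "character", concentration = "numeric",
                 domain = "character"))

.spectraDomains <- c("reflectance", "absorbance", "net_absorbance",
                     "derivative_1", "derivative_2", "snv", "msc")

setValidity("SpectraTable", function(object) {
  if (ncol(object@spectra) != length(object@grid@values))
    return("column count must equal the number of grid bands")
  if (nrow(object@spectra) != length(object@labels))
    return("every row needs a group label")
  if (length(object@concentration) &&
      length(object@concentration) != nrow(object@spectra))
    return("concentration must be absent or given for every row")
  if (length(object@domain) != 1L || !object@domain %in% .spectraDomains)
    return(paste("domain must be one of:", paste(.spectraDomains, collapse = ", ")))
  if (!is.numeric(object@spectra)) return("spectra must be numeric")
  TRUE
})

#' Hyperspectral data cube
#'
#' A 3-D array of lines x samples x bands, either raw digital numbers from
#' the sensor or radiometrically corrected reflectance fractions.
#'
#' @slot data 3-D numeric array `(lines, samples, bands)`.
#' @slot grid the [WavelengthGrid-class] of the band axis.
#' @slot kind `"raw"` (digital numbers) or `"reflectance"`.
#' @export
setClass("HyperCube",
  representation(data = "array", grid = "WavelengthGrid", kind = "character"))

setValidity("HyperCube", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("cube data must be a 3-D array")
  if (d[3L] != length(object@grid@values))
    return("third dimension must equal the number of grid bands")
  if (!object@kind %in% c("raw", "reflectance"))
    return("kind must be 'raw' or 'reflectance'")
  if (object@kind == "reflectance" && any(!is.finite(object@data)))
    return("reflectance cubes must contain only finite values")
  TRUE
})

#' Region-of-interest mask
#'
#' @slot mask logical matrix (lines x samples); `TRUE` marks ROI pixels.
#' @slot label single character label used for the extracted mean spectrum.
#' @export
setClass("ROIMask", representation(mask = "matrix", label = "character"))

setValidity("ROIMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (!any(object@mask)) return("mask must contain at least one TRUE pixel")
  if (length(object@label) != 1L) return("label must be a single string")
  TRUE
})

#' Result of a wavelength-selection run
#'
#' Ordered set of selected band indices with per-band diagnostics (the
#' Pearson correlation of each selected band with concentration) and
#' method-specific traces (projection norms for the successive projections
#' algorithm, per-run RMSE and retained counts for competitive adaptive
#' reweighted sampling).
#'
#' @slot method `"pearson"`, `"spa"` or `"cars"`.
#' @slot indices integer band indices into the grid, in selection order.
#' @slot wavelengths wavelengths (nm) of the selected bands.
#' @slot diagnostics method-specific list; always contains `pearson`, a
#'   data.frame with `wavelength`, `r` and `abs_r` for the selected bands.
#' @export
setClass("BandSelection",
  representation(method = "character", indices = "integer",
                 wavelengths = "numeric", diagnostics = "list"))

setValidity("BandSelection", function(object) {
  if (anyDuplicated(object@indices)) return("band indices must be distinct")
  if (length(object@wavelengths) != length(object@indices))
    return("wavelengths and indices must have equal length")
  if (!object@method %in% c("pearson", "spa", "cars"))
    return("method must be 'pearson', 'spa' or 'cars'")
  TRUE
})

#' Configuration of the synthetic spectra generator
#'
#' Bundles every knob of the synthetic standard-series / leaf generator:
#' the wavelength grid, the dilution series, the planted absorber bands,
#' baseline and leaf-matrix shapes, the saturation response and the noise
#' model.  `generatorConfig()` builds one with calibrated defaults.
#'
#' @slot nBands,loWavelength,hiWavelength grid specification.
#' @slot concentrations dilution series (ug/mL).
#' @slot replicates replicate spectra per group.
#' @slot absorberCenter,absorberSigma,absorberAmplitude primary planted band:
#'   centre (nm), Gaussian sigma (nm), absorbance per (ug/mL).
#' @slot minorCenter,minorSigma,minorAmplitude optional secondary band
#'   (amplitude 0 disables it).
#' @slot baselineCoef polynomial coefficients of the standard baseline
#'   absorbance in the scaled coordinate `(lambda - 1300)/400`.
#' @slot saturationKnee absorbance level (AU) where the response turns
#'   sublinear; `saturationHeadroom` is the residual dynamic range above it.
#' @slot suppressionGamma,suppressionCenter,suppressionWidth broadband
#'   high-concentration suppression: strength per AU of knee excess, and the
#'   centre/width (nm) of its sigmoid spectral shape.
#' @slot leafBase,leafSlope,waterAmplitude,waterCenter,waterSigma leaf
#'   matrix absorbance: flat base, linear structural slope across the range,
#'   and the water band.
#' @slot cultivarLoadings named numeric: effective absorber concentration
#'   (ug/mL) per cultivar.
#' @slot noiseSD reflectance-domain Gaussian noise sd.
#' @slot jitterSD per-replicate absorbance baseline jitter sd.
#' @slot reflectanceFloor positive clip floor keeping -log10 defined.
#' @slot seed integer master seed (per-stage streams are derived from it).
#' @export
setClass("GeneratorConfig",
  representation(nBands = "integer", loWavelength = "numeric",
    hiWavelength = "numeric", concentrations = "numeric",
    replicates = "integer",
    absorberCenter = "numeric", absorberSigma = "numeric",
    absorberAmplitude = "numeric",
    minorCenter = "numeric", minorSigma = "numeric",
    minorAmplitude = "numeric",
    baselineCoef = "numeric",
    saturationKnee = "numeric", saturationHeadroom = "numeric",
    suppressionGamma = "numeric", suppressionCenter = "numeric",
    suppressionWidth = "numeric",
    leafBase = "numeric", leafSlope = "numeric",
    waterAmplitude = "numeric", waterCenter = "numeric",
    waterSigma = "numeric",
    cultivarLoadings = "numeric",
    noiseSD = "numeric", jitterSD = "numeric",
    reflectanceFloor = "numeric", seed = "integer"))

setValidity("GeneratorConfig", function(object) {
  if (object@nBands < 2L) return("nBands must be >= 2")
  if (!is.finite(object@loWavelength) || !is.finite(object@hiWavelength) ||
      object@loWavelength >= object@hiWavelength)
    return("wavelength bounds must be finite with lo < hi")
  if (any(object@concentrations < 0)) return("concentrations must be non-negative")
  if (object@replicates < 2L) return("replicates must be >= 2")
  if (object@noiseSD < 0 || object@jitterSD < 0) return("noise sd must be >= 0")
  if (object@absorberAmplitude < 0 || object@minorAmplitude < 0)
    return("absorber amplitudes must be >= 0")
  if (object@absorberSigma <= 0 || object@minorSigma <= 0)
    return("absorber widths must be > 0")
  if (object@saturationKnee <= 0 || object@saturationHeadroom <= 0)
    return("saturation knee and headroom must be > 0")
  if (object@reflectanceFloor <= 0) return("reflectance floor must be > 0")
  if (length(object@cultivarLoadings) &&
      is.null(names(object@cultivarLoadings)))
    return("cultivarLoadings must be named by cultivar")
  TRUE
})

#' Per-group, per-band repeatability statistics
#'
#' Mean, standard deviation (n - 1 denominator) and coefficient of variation
#' (`CV% = 100 * SD / mean`) for every (group, band) cell, plus the
#' cross-group mean CV per band with its SD.
#'
#' @slot groups character vector of group names (matrix row order).
#' @slot wavelengths band wavelengths (nm) of the columns.
#' @slot bandIndices indices of the columns in the source grid.
#' @slot mean,sd,cv group x band matrices; `cv` is `NA` where the mean is 0.
#' @slot crossGroup data.frame with per-band mean CV across groups and its SD.
#' @export
setClass("GroupStats",
  representation(groups = "character", wavelengths = "numeric",
                 bandIndices = "integer", mean = "matrix", sd = "matrix",
                 cv = "matrix", crossGroup = "data.frame"))

#' Partial least squares regression model (NIPALS, single response)
#'
#' @slot nComponents number of latent components.
#' @slot weights p x a matrix of unit-norm weight vectors.
#' @slot loadings p x a matrix of X loadings.
#' @slot responseLoadings length-a response loadings q.
#' @slot scores n x a score matrix.
#' @slot coefficients length-p regression vector on centred data.
#' @slot intercept scalar intercept on the original scale.
#' @slot ssy per-component explained response variance q_a^2 * t_a't_a.
#' @slot xCenter,xScale,yCenter centring/scaling state.
#' @export
setClass("PLSRModel",
  representation(nComponents = "integer", weights = "matrix",
                 loadings = "matrix", responseLoadings = "numeric",
                 scores = "matrix", coefficients = "numeric",
                 intercept = "numeric", ssy = "numeric",
                 xCenter = "numeric", xScale = "numeric", yCenter = "numeric"))

#' Non-negative matrix factorization result
#'
#' @slot W sample x component weights (non-negative).
#' @slot H component x band spectra (non-negative).
#' @slot k number of components.
#' @slot errorTrace squared reconstruction error per recorded iteration
#'   (non-increasing).
#' @slot iterations iterations actually used.
#' @export
setClass("NMFResult",
  representation(W = "matrix", H = "matrix", k = "integer",
                 errorTrace = "numeric", iterations = "integer"))

#' Principal component analysis result with fixed sign convention
#'
#' @slot scores n x k score matrix.
#' @slot rotation p x k orthonormal component vectors; the largest-magnitude
#'   loading of each component is made positive so scores reproduce
#'   bit-for-bit.
#' @slot varianceFraction fraction of total variance per retained component.
#' @slot center column means removed before the decomposition.
#' @slot totalComponents rank of the centred data (for the sum-to-one check).
#' @export
setClass("PCAResult",
  representation(scores = "matrix", rotation = "matrix",
                 varianceFraction = "numeric", center = "numeric",
                 totalComponents = "integer"))

#' Regression quality metrics
#'
#' R-squared, root mean squared error and residual predictive deviation
#' (RPD = SD(y)/RMSE).  With the population-SD convention used by default,
#' the identity `RPD = (1 - R^2)^(-1/2)` holds exactly.
#'
#' @slot r2,rmse,rpd pooled values; `rpd` is `Inf` when `rmse` is 0.
#' @slot n number of prediction pairs.
#' @slot folds optional per-fold data.frame (columns fold, r2, rmse, rpd).
#' @export
setClass("RegressionMetrics",
  representation(r2 = "numeric", rmse = "numeric", rpd = "numeric",
                 n = "integer", folds = "data.frame"))

#' Configuration of the 1-D convolutional regressor
#'
#' Architecture: valid (unpadded) 1-D convolution (`filters` x `kernel`,
#' rectified-linear) -> max-pool (`pool`, floor) -> flatten -> dense
#' (`denseUnits`, rectified-linear) -> single linear output.
#'
#' @slot nInputBands number of input bands.
#' @slot filters,kernel,pool,denseUnits architecture sizes.
#' @slot epochs,batchSize,learningRate training hyperparameters
#'   (adaptive-moment optimizer, mean squared error loss).
#' @slot seed integer seed for initialization and shuffling.
#' @slot scaleTarget z-score the target during training (inverted at
#'   prediction).
#' @export
setClass("CNNConfig",
  representation(nInputBands = "integer", filters = "integer",
                 kernel = "integer", pool = "integer", denseUnits = "integer",
                 epochs = "integer", batchSize = "integer",
                 learningRate = "numeric", seed = "integer",
                 scaleTarget = "logical"))

setValidity("CNNConfig", function(object) {
  counts <- c(object@nInputBands, object@filters, object@kernel, object@pool,
              object@denseUnits, object@epochs, object@batchSize)
  if (any(counts < 1L)) return("all counts must be positive")
  if (object@kernel > object@nInputBands)
    return("kernel width must not exceed the number of input bands")
  convLen <- object@nInputBands - object@kernel + 1L
  if (convLen %/% object@pool < 1L)
    return(sprintf("pooled length is %d; need at least 1 (conv length %d, pool %d)",
                   convLen %/% object@pool, convLen, object@pool))
  if (object@learningRate <= 0) return("learning rate must be positive")
  TRUE
})

#' Trained 1-D convolutional regressor
#'
#' Prediction is a pure function of the learned parameters, the stored
#' per-band standardization state (computed from training rows only) and the
#' input.
#'
#' @slot config the [CNNConfig-class] used.
#' @slot params named list of weight arrays.
#' @slot xCenter,xScale per-band standardization from the training rows.
#' @slot yCenter,yScale target scaling state (identity when disabled).
#' @slot lossTrace mean training loss per epoch.
#' @slot bandIndices optional band indices the model was trained on.
#' @slot bandWavelengths wavelengths of those bands (nm).
#' @slot trainRange range of training targets, used to flag extrapolation.
#' @export
setClass("CNNRegressor",
  representation(config = "CNNConfig", params = "list",
                 xCenter = "numeric", xScale = "numeric",
                 yCenter = "numeric", yScale = "numeric",
                 lossTrace = "numeric", bandIndices = "integer",
                 bandWavelengths = "numeric", trainRange = "numeric"))

#' Standard-to-leaf transfer report
#'
#' Collects per-cultivar predicted-concentration distributions, the median
#' dichotomization threshold with binary labels, the ROC curve with its AUC,
#' and (optionally) the combined PCA of standards and leaves.
#'
#' @slot predictions data.frame with columns `label`, `prediction`,
#'   `extrapolated`.
#' @slot cultivarSummary data.frame: per-cultivar n, median, q25, q75,
#'   extrapolation count.
#' @slot threshold median of all pooled predictions (ug/mL); `NA` before
#'   dichotomization.
#' @slot classLabels `"high"`/`"low"` per prediction row.
#' @slot degenerate TRUE when all predictions are equal.
#' @slot roc data.frame of ROC points; empty before [rocAuc()] is applied.
#' @slot auc area under the ROC curve (rank method, half-credit ties).
#' @slot extrapolationRange training target range used for the flag.
#' @export
setClass("TransferReport",
  representation(predictions = "data.frame", cultivarSummary = "data.frame",
                 threshold = "numeric", classLabels = "character",
                 degenerate = "logical", roc = "data.frame", auc = "numeric",
                 extrapolationRange = "numeric"))
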