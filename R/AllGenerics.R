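#' Number of spectral bands
#' @param x an object carrying a wavelength grid.
#' @return integer band count.
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' Band-centre wavelengths (nm)
#' @param x an object carrying a wavelength grid.
#' @return numeric vector of wavelengths.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Index of the band nearest a wavelength
#'
#' Resolves a nominal wavelength (e.g. the 923 nm absorber band) to the grid
#' band minimizing `|lambda_i - x|`.
#'
#' @param x an object carrying a wavelength grid.
#' @param wavelength numeric wavelength(s), nm.
#' @return integer band index (vectorized over `wavelength`).
#' @export
setGeneric("nearestBand", function(x, wavelength) standardGeneric("nearestBand"))

#' Spectra matrix of a table
#' @param x a [SpectraTable-class].
#' @return numeric matrix, rows = replicate spectra.
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))

#' Per-row group labels
#' @param x a [SpectraTable-class].
#' @return character vector.
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' Per-row concentrations (ug/mL)
#' @param x a [SpectraTable-class].
#' @return numeric vector, or `NULL` for cultivar-labelled tables.
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' Spectral domain tag
#' @param x a [SpectraTable-class].
#' @return one of `"reflectance"`, `"absorbance"`, `"net_absorbance"`,
#'   `"derivative_1"`, `"derivative_2"`, `"snv"`, `"msc"`.
#' @export
setGeneric("spectralDomain", function(x) standardGeneric("spectralDomain"))

#' Cube data array
#' @param x a [HyperCube-class].
#' @return 3-D numeric array (lines, samples, bands).
#' @export
setGeneric("cubeData", function(x) standardGeneric("cubeData"))

#' Selected band indices
#' @param x a [BandSelection-class].
#' @return integer vector in selection order.
#' @export
setGeneric("selectedBands", function(x) standardGeneric("selectedBands"))
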