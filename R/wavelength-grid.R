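#' Build a linear wavelength grid
#'
#' Constructs an `nBands`-point linear grid with both endpoints included,
#' mirroring a push-broom NIR sensor sampling a fixed spectral window.  The
#' default dimensions elsewhere in the package are 512 bands over
#' 900--1700 nm, i.e. a sampling interval of about 1.57 nm (the optical
#' resolution of such a sensor is typically coarser; sampling and resolution
#' are distinct).
#'
#' @param nBands number of bands (>= 2).
#' @param lo,hi first and last wavelength (nm), `lo < hi`.
#' @return a [WavelengthGrid-class].
#' @examples
#' g <- makeWavelengthGrid(512, 900, 1700)
#' nBands(g)
#' nearestBand(g, 923)
#' @export
makeWavelengthGrid <- function(nBands, lo, hi) {
  stopIfNot(is.finite(lo) && is.finite(hi), "grid bounds must be finite")
  stopIfNot(lo < hi, "grid bounds must satisfy lo < hi")
  stopIfNot(nBands >= 2, "need at least 2 bands")
  new("WavelengthGrid", values = seq(lo, hi, length.out = as.integer(nBands)))
}

#' @rdname nBands
#' @export
setMethod("nBands", "WavelengthGrid", function(x) length(x@values))

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "WavelengthGrid", function(x) x@values)

#' @rdname nearestBand
#' @export
setMethod("nearestBand", "WavelengthGrid", function(x, wavelength) {
  stopIfNot(all(is.finite(wavelength)), "wavelength must be finite")
  vapply(wavelength, function(w) which.min(abs(x@values - w)), integer(1))
})

setMethod("show", "WavelengthGrid", function(object) {
  v <- object@values
  cat(sprintf("WavelengthGrid: %d bands, %.1f-%.1f nm (spacing %.3f nm)\n",
              length(v), v[1L], v[length(v)], mean(diff(v))))
})
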