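#' @rdname cubeData
#' @export
setMethod("cubeData", "HyperCube", function(x) x@data)

#' @rdname nBands
#' @export
setMethod("nBands", "HyperCube", function(x) nBands(x@grid))

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "HyperCube", function(x) wavelengths(x@grid))

#' @rdname nearestBand
#' @export
setMethod("nearestBand", "HyperCube",
          function(x, wavelength) nearestBand(x@grid, wavelength))

setMethod("show", "HyperCube", function(object) {
  d <- dim(object@data)
  cat(sprintf("HyperCube [%s]: %d lines x %d samples x %d bands\n",
              object@kind, d[1L], d[2L], d[3L]))
})

#' Radiometric correction of a raw cube to reflectance
#'
#' Applies the standard flat-field correction
#' `R = (I_raw - I_dark) / (I_white - I_dark)` element-wise.  Pixels where
#' the denominator falls below `epsilon` are not divided: they are set to
#' `NA`, counted, and excluded from downstream ROI means.  Negative
#' corrected values (raw below dark, possible under noise) are clipped to 0
#' and counted.
#'
#' @param raw,dark,white raw-kind [HyperCube-class]s of identical shape and
#'   grid.
#' @param epsilon division guard in digital-number units.
#' @return a reflectance-kind [HyperCube-class]; attributes
#'   `invalidPixels` and `clippedPixels` carry the counts.
#' @export
radiometricCorrect <- function(raw, dark, white, epsilon = 1e-9) {
  stopIfNot(identical(dim(raw@data), dim(dark@data)) &&
            identical(dim(raw@data), dim(white@data)),
            "raw, dark and white cubes must have identical shapes")
  stopIfNot(isTRUE(all.equal(wavelengths(raw), wavelengths(white))) &&
            isTRUE(all.equal(wavelengths(raw), wavelengths(dark))),
            "raw, dark and white cubes must share one wavelength grid")
  denom <- white@data - dark@data
  bad <- denom <= epsilon
  stopIfNot(!all(bad), "white - dark is degenerate everywhere")
  R <- (raw@data - dark@data) / ifelse(bad, 1, denom)
  R[bad] <- NA_real_
  clipped <- sum(R < 0, na.rm = TRUE)
  R[!is.na(R) & R < 0] <- 0
  nInvalid <- sum(bad)
  if (nInvalid > 0) R[is.na(R)] <- 0  # sentinel after counting
  out <- new("HyperCube", data = R, grid = raw@grid, kind = "reflectance")
  attr(out@data, "invalidPixels") <- nInvalid
  attr(out@data, "clippedPixels") <- clipped
  out
}

#' Rectangular region-of-interest mask
#'
#' @param lines,samples spatial dimensions of the target cube.
#' @param rows,cols integer ranges of the rectangle.
#' @param label label attached to the extracted mean spectrum.
#' @return an [ROIMask-class].
#' @export
roiRect <- function(lines, samples, rows, cols, label) {
  m <- matrix(FALSE, lines, samples)
  m[rows, cols] <- TRUE
  new("ROIMask", mask = m, label = as.character(label))
}

#' Extract per-ROI mean spectra from a reflectance cube
#'
#' Computes, for each mask, the per-band mean over the mask's pixels.  This
#' is the bridge from imaging to chemometrics: each ROI contributes one row
#' of the resulting spectra table.
#'
#' @param cube a reflectance-kind [HyperCube-class].
#' @param masks a list of [ROIMask-class] objects (or a single mask).
#' @return a reflectance [SpectraTable-class], one row per mask, labelled by
#'   the mask labels.
#' @export
extractROISpectra <- function(cube, masks) {
  stopIfNot(cube@kind == "reflectance", "cube must be reflectance-kind")
  if (is(masks, "ROIMask")) masks <- list(masks)
  d <- dim(cube@data)
  rows <- t(vapply(masks, function(m) {
    validObject(m)
    stopIfNot(identical(dim(m@mask), d[1:2]),
              "mask shape must match the cube's spatial dimensions")
    idx <- which(m@mask)
    flat <- matrix(cube@data, nrow = d[1L] * d[2L], ncol = d[3L])
    colMeans(flat[idx, , drop = FALSE])
  }, numeric(d[3L])))
  spectraTable(rows, cube@grid,
               labels = vapply(masks, function(m) m@label, character(1)),
               domain = "reflectance")
}

#' Single-band false-color map
#'
#' Pulls the band nearest the requested wavelength and min--max scales it to
#' `[0, 1]` for rendering; the raw range is recorded so intensity remains
#' interpretable.  A constant band degrades to all zeros by convention.
#'
#' @param cube a reflectance-kind [HyperCube-class].
#' @param wavelength requested wavelength (nm); must lie within the grid.
#' @return list of class `"falseColorMap"`: `image` (lines x samples in
#'   `[0,1]`), `bandIndex`, `wavelength` (actual band centre), `range`
#'   (raw min/max).
#' @export
falseColorBandMap <- function(cube, wavelength) {
  stopIfNot(cube@kind == "reflectance", "cube must be reflectance-kind")
  wl <- wavelengths(cube)
  stopIfNot(wavelength >= wl[1L] && wavelength <= wl[length(wl)],
            "wavelength outside the grid range")
  b <- nearestBand(cube, wavelength)
  img <- cube@data[, , b]
  rng <- range(img)
  scaled <- if (rng[1L] == rng[2L]) array(0, dim(img)) else
    (img - rng[1L]) / (rng[2L] - rng[1L])
  structure(list(image = scaled, bandIndex = b, wavelength = wl[b],
                 range = rng), class = "falseColorMap")
}

#' Write a false-color map as PNG with a text sidecar
#'
#' @param map a `"falseColorMap"` from [falseColorBandMap()].
#' @param path output PNG path; the sidecar is `paste0(path, ".txt")`.
#' @return `path`, invisibly.
#' @export
writeFalseColorPNG <- function(map, path) {
  png::writePNG(map$image, target = path)
  writeLines(c(sprintf("band_index: %d", map$bandIndex),
               sprintf("wavelength_nm: %.4f", map$wavelength),
               sprintf("raw_min: %.8g", map$range[1L]),
               sprintf("raw_max: %.8g", map$range[2L])),
             paste0(path, ".txt"))
  invisible(path)
}
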