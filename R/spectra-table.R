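#' Construct a spectra table
#'
#' @param spectra numeric matrix, rows = replicate spectra, cols = bands.
#' @param grid a [WavelengthGrid-class] with `ncol(spectra)` bands.
#' @param labels per-row group labels (concentration group or cultivar).
#' @param concentration optional per-row concentration (ug/mL).
#' @param domain spectral domain tag; new tables are usually `"reflectance"`.
#' @return a [SpectraTable-class].
#' @export
spectraTable <- function(spectra, grid, labels, concentration = numeric(0),
                         domain = "reflectance") {
  new("SpectraTable", spectra = as.matrix(spectra), grid = grid,
      labels = as.character(labels),
      concentration = as.numeric(concentration), domain = domain)
}

#' @rdname spectra
#' @export
setMethod("spectra", "SpectraTable", function(x) x@spectra)

#' @rdname groupLabels
#' @export
setMethod("groupLabels", "SpectraTable", function(x) x@labels)

#' @rdname concentrations
#' @export
setMethod("concentrations", "SpectraTable",
          function(x) if (length(x@concentration)) x@concentration else NULL)

#' @rdname spectralDomain
#' @export
setMethod("spectralDomain", "SpectraTable", function(x) x@domain)

#' @rdname nBands
#' @export
setMethod("nBands", "SpectraTable", function(x) nBands(x@grid))

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SpectraTable", function(x) wavelengths(x@grid))

#' @rdname nearestBand
#' @export
setMethod("nearestBand", "SpectraTable",
          function(x, wavelength) nearestBand(x@grid, wavelength))

setMethod("show", "SpectraTable", function(object) {
  cat(sprintf("SpectraTable: %d spectra x %d bands [%s]\n",
              nrow(object@spectra), ncol(object@spectra), object@domain))
  tab <- table(object@labels)
  cat(sprintf("  %d groups: %s\n", length(tab),
              paste(utils::head(names(tab), 8L), collapse = ", ")))
  if (length(object@concentration))
    cat(sprintf("  concentrations: %s ug/mL\n",
                paste(sort(unique(object@concentration)), collapse = ", ")))
})

#' Subset a spectra table to a set of bands
#'
#' Returns a plain matrix restricted to the given band indices (the result
#' no longer spans the full grid, so it is not a `SpectraTable`).
#'
#' @param x a [SpectraTable-class].
#' @param bands integer band indices or a [BandSelection-class].
#' @return numeric matrix with one column per requested band.
#' @export
bandMatrix <- function(x, bands) {
  idx <- if (is(bands, "BandSelection")) bands@indices else as.integer(bands)
  stopIfNot(all(idx >= 1L & idx <= nBands(x)), "band index out of range")
  m <- x@spectra[, idx, drop = FALSE]
  colnames(m) <- sprintf("%.1f", wavelengths(x)[idx])
  m
}

#' Write / read a spectra table as CSV
#'
#' Plain-text interchange format: a `# domain:` comment line, then a header
#' row, then one row per spectrum.  First column is the group label, second
#' the concentration in ug/mL (empty for cultivar-labelled tables), the
#' remaining columns are named by wavelength with one decimal.
#'
#' @param x a [SpectraTable-class].
#' @param path file path.
#' @return `writeSpectraCSV` returns `path` invisibly; `readSpectraCSV`
#'   returns a [SpectraTable-class].
#' @export
writeSpectraCSV <- function(x, path) {
  wl <- sprintf("%.1f", wavelengths(x))
  conc <- if (length(x@concentration)) x@concentration else
    rep(NA_real_, nrow(x@spectra))
  df <- data.frame(label = x@labels, concentration = conc,
                   x@spectra, check.names = FALSE)
  colnames(df) <- c("label", "concentration", wl)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# domain: %s", x@domain), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSpectraCSV
#' @export
readSpectraCSV <- function(path) {
  first <- readLines(path, n = 1L)
  domain <- if (startsWith(first, "# domain:"))
    trimws(sub("# domain:", "", first, fixed = TRUE)) else "reflectance"
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  wl <- as.numeric(colnames(df)[-(1:2)])
  conc <- df[[2L]]
  spectraTable(as.matrix(df[, -(1:2), drop = FALSE]),
               new("WavelengthGrid", values = wl),
               labels = df[[1L]],
               concentration = if (all(is.na(conc))) numeric(0) else conc,
               domain = domain)
}
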