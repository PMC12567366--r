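#' Convert reflectance to absorbance
#'
#' `A = -log10(R)` element-wise.  Requires a reflectance-domain table whose
#' values are strictly positive (the generator and the radiometric
#' correction both clip at a positive floor, so this holds by
#' construction).
#'
#' @param x a reflectance [SpectraTable-class].
#' @return an absorbance [SpectraTable-class].
#' @export
toAbsorbance <- function(x) {
  stopIfNot(spectralDomain(x) == "reflectance",
            "toAbsorbance expects a reflectance table")
  stopIfNot(all(x@spectra > 0), "reflectance must be > 0 (apply a floor first)")
  out <- x
  out@spectra <- -log10(x@spectra)
  out@domain <- "absorbance"
  out
}

#' Subtract the blank group's mean absorbance
#'
#' Background correction against the zero-concentration (blank) group: the
#' blank's mean absorbance spectrum is subtracted from every row, so blank
#' rows become approximately zero-mean noise and the remaining signal is the
#' analyte's net absorbance.
#'
#' @param x an absorbance [SpectraTable-class].
#' @param blankLabel group label of the blank (default `"0"`).
#' @return a net-absorbance [SpectraTable-class].
#' @export
netAbsorbance <- function(x, blankLabel = "0") {
  stopIfNot(spectralDomain(x) %in% c("absorbance", "net_absorbance"),
            "netAbsorbance expects an absorbance table")
  sel <- x@labels == blankLabel
  stopIfNot(any(sel), "blank group not found: ", blankLabel)
  blank <- colMeans(x@spectra[sel, , drop = FALSE])
  out <- x
  out@spectra <- sweep(x@spectra, 2L, blank)
  out@domain <- "net_absorbance"
  out
}

#' Savitzky-Golay derivative of each spectrum
#'
#' Smoothed 1st or 2nd derivative per row, taken with respect to band index
#' (on a linear grid this differs from d/d(nm) by a constant factor only).
#' Edges are handled by the asymmetric polynomial fits of the
#' Savitzky-Golay projection matrix.
#'
#' @param x a [SpectraTable-class].
#' @param order derivative order, 1 or 2.
#' @param window odd filter length, `window > polyorder`.
#' @param polyorder polynomial order, `>= order`.
#' @return a [SpectraTable-class] with domain `"derivative_1"` or
#'   `"derivative_2"`.
#' @export
spectralDerivative <- function(x, order = 1L, window = 11L, polyorder = 2L) {
  stopIfNot(order %in% c(1L, 2L), "order must be 1 or 2")
  stopIfNot(window %% 2L == 1L, "window must be odd")
  stopIfNot(window > polyorder, "window must exceed polyorder")
  stopIfNot(polyorder >= order, "polyorder must be >= derivative order")
  stopIfNot(window <= nBands(x), "window exceeds the number of bands")
  out <- x
  out@spectra <- t(apply(x@spectra, 1L, function(row)
    signal::sgolayfilt(row, p = polyorder, n = window, m = order, ts = 1)))
  out@domain <- paste0("derivative_", order)
  out
}

#' Standard normal variate transform
#'
#' Per-row centring and scaling to unit standard deviation, the classic
#' scatter correction for diffuse-reflectance spectra.
#'
#' @param x a [SpectraTable-class] with >= 2 bands.
#' @return an SNV-domain [SpectraTable-class].
#' @export
snv <- function(x) {
  stopIfNot(nBands(x) >= 2L, "need at least 2 bands")
  s <- apply(x@spectra, 1L, stats::sd)
  if (any(s == 0)) stop("zero-variance row(s): ",
                        paste(which(s == 0), collapse = ", "), call. = FALSE)
  out <- x
  out@spectra <- (x@spectra - rowMeans(x@spectra)) / s
  out@domain <- "snv"
  out
}

#' Multiplicative scatter correction
#'
#' Each row is regressed on a reference spectrum by ordinary least squares,
#' `row ~ a + b * reference`, and replaced by `(row - a)/b`.  With the
#' default reference (the mean spectrum of the table), MSC removes additive
#' and multiplicative scatter differences between replicates.
#'
#' @param x a [SpectraTable-class] with >= 2 bands.
#' @param reference reference spectrum; defaults to the table's mean.
#' @return an MSC-domain [SpectraTable-class].
#' @export
msc <- function(x, reference = NULL) {
  stopIfNot(nBands(x) >= 2L, "need at least 2 bands")
  if (is.null(reference)) reference <- colMeans(x@spectra)
  stopIfNot(length(reference) == nBands(x), "reference length mismatch")
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  stopIfNot(denom > 0, "reference spectrum is constant")
  out <- x
  out@spectra <- t(apply(x@spectra, 1L, function(row) {
    b <- sum((row - mean(row)) * rc) / denom
    if (abs(b) < 1e-12)
      stop("MSC slope ~ 0 for a row; cannot correct", call. = FALSE)
    a <- mean(row) - b * mean(reference)
    (row - a) / b
  }))
  out@domain <- "msc"
  out
}

#' Per-group repeatability statistics
#'
#' For each (group, band) cell: mean, sample standard deviation (n - 1) and
#' coefficient of variation `CV% = 100 * SD/mean` (flagged `NA` where the
#' mean is zero).  Also returns, per band, the mean CV across groups with
#' its SD -- the cross-group repeatability profile used to vet selected
#' wavelengths.
#'
#' @param x a [SpectraTable-class]; every group needs >= 2 rows.
#' @param bands optional band subset (indices or a [BandSelection-class]).
#' @return a [GroupStats-class].
#' @export
groupStats <- function(x, bands = NULL) {
  idx <- if (is.null(bands)) seq_len(nBands(x)) else
    if (is(bands, "BandSelection")) bands@indices else as.integer(bands)
  X <- x@spectra[, idx, drop = FALSE]
  groups <- unique(x@labels)
  counts <- table(x@labels)
  if (any(counts < 2L))
    stop("singleton group(s): ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  mu <- t(vapply(groups, function(g) colMeans(X[x@labels == g, , drop = FALSE]),
                 numeric(ncol(X))))
  sdm <- t(vapply(groups, function(g)
    apply(X[x@labels == g, , drop = FALSE], 2L, stats::sd), numeric(ncol(X))))
  cv <- 100 * sdm / mu
  cv[mu == 0] <- NA_real_
  cross <- data.frame(wavelength = wavelengths(x)[idx],
                      meanCV = colMeans(cv, na.rm = TRUE),
                      sdCV = apply(cv, 2L, stats::sd, na.rm = TRUE))
  new("GroupStats", groups = groups, wavelengths = wavelengths(x)[idx],
      bandIndices = as.integer(idx), mean = mu, sd = sdm, cv = cv,
      crossGroup = cross)
}

setMethod("show", "GroupStats", function(object) {
  cat(sprintf("GroupStats: %d groups x %d bands; %.1f%% of cells with CV <= 5%%\n",
              length(object@groups), length(object@wavelengths),
              100 * mean(object@cv <= 5, na.rm = TRUE)))
})

#' Export group statistics as tidy CSV
#'
#' Long format: one row per (group, wavelength) with mean, sd and cv.
#'
#' @param stats a [GroupStats-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeGroupStatsCSV <- function(stats, path) {
  df <- expand.grid(group = stats@groups, wavelength = stats@wavelengths,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$mean <- as.vector(stats@mean)
  df$sd <- as.vector(stats@sd)
  df$cv <- as.vector(stats@cv)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
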