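# ENVI-format cube I/O.  Dialect: ASCII header file alongside a flat binary
# image; BIL interleave, little-endian, float32 (data type 4) for
# reflectance and uint16 (data type 12) for raw digital numbers.

.enviDataType <- function(kind) if (kind == "raw") 12L else 4L

#' Write / read a hyperspectral cube in ENVI format
#'
#' `writeENVI` writes `path` (flat binary, BIL interleave, little-endian)
#' plus `paste0(path, ".hdr")` (ASCII header with samples, lines, bands,
#' interleave, data type and the wavelength list).  Raw-kind cubes are
#' stored as unsigned 16-bit integers, reflectance-kind as 32-bit floats.
#' `readENVI` reverses the operation; a second write/read cycle reproduces
#' the file bit-exactly.
#'
#' @param cube a [HyperCube-class].
#' @param path binary file path (header is `paste0(path, ".hdr")`).
#' @return `writeENVI`: `path` invisibly; `readENVI`: a [HyperCube-class].
#' @export
writeENVI <- function(cube, path) {
  d <- dim(cube@data)
  dtype <- .enviDataType(cube@kind)
  hdr <- c("ENVI",
           sprintf("samples = %d", d[2L]),
           sprintf("lines = %d", d[1L]),
           sprintf("bands = %d", d[3L]),
           "header offset = 0",
           "file type = ENVI Standard",
           sprintf("data type = %d", dtype),
           "interleave = bil",
           "byte order = 0",
           sprintf("wavelength = { %s }",
                   paste(sprintf("%.6f", wavelengths(cube)), collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  # BIL: lines outermost, then bands, samples fastest
  v <- as.vector(aperm(cube@data, c(2L, 3L, 1L)))
  con <- file(path, "wb")
  on.exit(close(con))
  if (dtype == 12L) {
    writeBin(as.integer(round(v)), con, size = 2L, endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' @rdname writeENVI
#' @export
readENVI <- function(path) {
  hdrPath <- paste0(path, ".hdr")
  stopIfNot(file.exists(hdrPath), "missing ENVI header: ", hdrPath)
  lines <- readLines(hdrPath, warn = FALSE)
  getNum <- function(key) {
    ln <- grep(sprintf("^%s\\s*=", key), lines, value = TRUE)
    stopIfNot(length(ln) == 1L, "header key missing: ", key)
    as.numeric(sub(".*=\\s*", "", ln))
  }
  nSamples <- as.integer(getNum("samples"))
  nLines <- as.integer(getNum("lines"))
  nB <- as.integer(getNum("bands"))
  dtype <- as.integer(getNum("data type"))
  il <- tolower(sub(".*=\\s*", "", grep("^interleave", lines, value = TRUE)))
  stopIfNot(identical(trimws(il), "bil"), "only BIL interleave is supported")
  wlLine <- paste(lines[grep("^wavelength", lines)[1L]:length(lines)],
                  collapse = " ")
  wl <- as.numeric(strsplit(gsub(".*\\{|\\}.*", "", wlLine), ",")[[1L]])
  stopIfNot(length(wl) == nB, "wavelength list length mismatch")
  n <- nSamples * nLines * nB
  con <- file(path, "rb")
  on.exit(close(con))
  v <- if (dtype == 12L) {
    readBin(con, "integer", n = n, size = 2L, signed = FALSE,
            endian = "little")
  } else if (dtype == 4L) {
    readBin(con, "numeric", n = n, size = 4L, endian = "little")
  } else stop("unsupported ENVI data type: ", dtype)
  arr <- aperm(array(as.numeric(v), dim = c(nSamples, nB, nLines)),
               c(3L, 1L, 2L))
  new("HyperCube", data = arr,
      grid = new("WavelengthGrid", values = wl),
      kind = if (dtype == 12L) "raw" else "reflectance")
}
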