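# Sinogram container and volume export.
#
# The container is a single self-describing file: a 4-byte magic "DTS1", a
# 4-byte little-endian header length, a UTF-8 JSON header carrying the
# acquisition attributes, then the raw payload as little-endian IEEE-754
# doubles (angles, real parts, imaginary parts, in R column-major order).
# Doubles are written bit-for-bit, so a write/read round trip is lossless.

SINO_MAGIC <- charToRaw("DTS1")
REQUIRED_ATTRS <- c("wavelength_px", "medium_index", "detector_distance_px",
                    "approximation_tag", "shape")

#' Write a sinogram container
#'
#' Serializes a [complex_sinogram()] (or filtered `scattering_data`) with
#' its full acquisition metadata. The round trip through [read_sinogram()]
#' is bit-identical.
#'
#' @param path destination file path.
#' @param sinogram a `complex_sinogram` or `scattering_data` object.
#' @param seed optional integer recorded in the header for provenance.
#' @return `path`, invisibly.
#' @export
write_sinogram <- function(path, sinogram, seed = NULL) {
  if (inherits(sinogram, "complex_sinogram")) {
    fields <- sinogram$fields; tag <- "field"
  } else if (inherits(sinogram, "scattering_data")) {
    fields <- sinogram$data + 0i; tag <- sinogram$approximation
  } else stop("sinogram must be a complex_sinogram or scattering_data")
  geo <- sinogram$geometry
  header <- list(
    format = "difftomo-sinogram", version = 1L,
    shape = as.integer(dim(fields)),
    wavelength_px = geo$wavelength,
    medium_index = geo$medium_index,
    detector_distance_px = geo$detector_distance,
    approximation_tag = tag,
    creator = paste0("difftomo ", tryCatch(
      as.character(utils::packageVersion("difftomo")),
      error = function(e) "dev")))
  if (!is.null(seed)) header$seed <- as.integer(seed)
  hjson <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(SINO_MAGIC, con)
  writeBin(length(hjson), con, size = 4, endian = "little")
  writeBin(hjson, con)
  writeBin(sinogram$angles, con, size = 8, endian = "little")
  writeBin(as.vector(Re(fields)), con, size = 8, endian = "little")
  writeBin(as.vector(Im(fields)), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a sinogram container
#'
#' Validates the header (every required attribute must be present; the
#' payload size must match the declared shape) and reconstructs the stored
#' object: a [complex_sinogram()] for raw fields, or a `scattering_data`
#' object for Born/Rytov/Radon-filtered data.
#'
#' @param path container file written by [write_sinogram()].
#' @return a `complex_sinogram` or `scattering_data` object.
#' @export
read_sinogram <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  if (!identical(magic, SINO_MAGIC))
    stop("not a difftomo sinogram container (bad magic)")
  hlen <- readBin(con, "integer", 1, size = 4, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  missing_attr <- setdiff(REQUIRED_ATTRS, names(header))
  if (length(missing_attr) > 0)
    stop(sprintf("container header is missing attribute(s): %s",
                 paste(missing_attr, collapse = ", ")))
  shape <- as.integer(header$shape)
  n_ang <- shape[1]
  n_total <- prod(shape)
  angles <- readBin(con, "double", n_ang, size = 8, endian = "little")
  re <- readBin(con, "double", n_total, size = 8, endian = "little")
  im <- readBin(con, "double", n_total, size = 8, endian = "little")
  if (length(angles) != n_ang || length(re) != n_total ||
      length(im) != n_total)
    stop("payload size does not match the declared shape")
  fields <- array(complex(real = re, imaginary = im), shape)
  if (length(shape) == 2) fields <- matrix(fields, shape[1], shape[2])
  geo <- imaging_geometry(header$wavelength_px, header$medium_index,
                          header$detector_distance_px)
  if (identical(header$approximation_tag, "field"))
    complex_sinogram(fields, angles, geo)
  else if (header$approximation_tag == "radon")
    scattering_data(Re(fields), angles, geo, "radon")
  else
    scattering_data(fields, angles, geo, header$approximation_tag)
}

#' Export a map as a 32-bit float TIFF stack
#'
#' One page per z slice (a single page for 2D maps), values written
#' unscaled. Complex maps must state which part to export.
#'
#' @param path destination `.tif` path.
#' @param map an [ri_map()], [object_map()] or bare array.
#' @param part for complex maps: `"real"`, `"imag"` or `"mod"`; rejected if
#'   omitted for complex input.
#' @return `path`, invisibly.
#' @export
export_volume_tiff <- function(path, map, part = NULL) {
  x <- if (inherits(map, "ri_map")) map$n
  else if (inherits(map, "object_map")) map$f
  else map
  if (is.complex(x)) {
    if (is.null(part))
      stop("complex map: choose part = \"real\", \"imag\" or \"mod\"")
    x <- switch(match.arg(part, c("real", "imag", "mod")),
                real = Re(x), imag = Im(x), mod = Mod(x))
  }
  d <- dim(x)
  pages <- if (length(d) == 2) list(x)
  else lapply(seq_len(d[1]), function(z) x[z, , ])
  write_float_tiff(path, pages)
  invisible(path)
}

# Minimal 32-bit IEEE-float TIFF writer (little-endian, uncompressed, one
# strip and one IFD per page). Needed because the available TIFF writers
# only store samples clamped to [0, 1]; tiff::readTIFF reads the result.
write_float_tiff <- function(path, pages) {
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    u16(tag); u16(type); u32(count); u32(value)
  }
  n_pages <- length(pages)
  sizes <- vapply(pages, function(p) length(p) * 4L, integer(1))
  data_off <- 8L + c(0L, cumsum(sizes))[seq_len(n_pages)]
  ifd_bytes <- 2L + 10L * 12L + 4L
  ifd_off <- 8L + sum(sizes) + (seq_len(n_pages) - 1L) * ifd_bytes
  writeBin(charToRaw("II"), con); u16(42L); u32(ifd_off[1])
  for (p in pages)  # TIFF scanlines are rows: transpose column-major R data
    writeBin(as.vector(t(p)), con, size = 4, endian = "little")
  for (i in seq_len(n_pages)) {
    nr <- nrow(pages[[i]]); nc <- ncol(pages[[i]])
    u16(10L)                                  # entry count
    entry(256L, 4L, 1L, nc)                   # ImageWidth
    entry(257L, 4L, 1L, nr)                   # ImageLength
    entry(258L, 3L, 1L, 32L)                  # BitsPerSample
    entry(259L, 3L, 1L, 1L)                   # Compression = none
    entry(262L, 3L, 1L, 1L)                   # Photometric = BlackIsZero
    entry(273L, 4L, 1L, data_off[i])          # StripOffsets
    entry(277L, 3L, 1L, 1L)                   # SamplesPerPixel
    entry(278L, 4L, 1L, nr)                   # RowsPerStrip
    entry(279L, 4L, 1L, sizes[i])             # StripByteCounts
    entry(339L, 3L, 1L, 3L)                   # SampleFormat = IEEE float
    u32(if (i < n_pages) ifd_off[i + 1] else 0L)  # next IFD
  }
  invisible(path)
}

#' Read a float TIFF stack back into an array
#'
#' Inverse of [export_volume_tiff()]: a single page becomes a matrix, a
#' multi-page stack an array `(Nz, Ny, Nx)`.
#'
#' @param path TIFF file path.
#' @return numeric matrix or 3D array.
#' @export
read_volume_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 1) return(pages[[1]])
  d <- dim(pages[[1]])
  out <- array(0, c(length(pages), d[1], d[2]))
  for (z in seq_along(pages)) out[z, , ] <- pages[[z]]
  out
}
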