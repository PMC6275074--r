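#' Hypercube container
#'
#' A 3-D intensity array in `(line, sample, band)` order plus its wavelength
#' grid and a `kind` flag tracking the processing state. Lines and samples
#' are indexed 1-based in R; band `b` corresponds to `wavelengths(cube)[b]`.
#'
#' @param data 3-D numeric array, `lines x samples x bands`.
#' @param wavelength Wavelength grid, length equal to `dim(data)[3]`.
#' @param kind One of `"raw"`, `"reflectance_percent"`, `"absorbance"`.
#' @return A `hypercube` object.
#' @export
hypercube <- function(data, wavelength,
                      kind = c("raw", "reflectance_percent", "absorbance")) {
  kind <- match.arg(kind)
  if (length(dim(data)) != 3L)
    stop("cube data must be a 3-D array (lines x samples x bands)",
         call. = FALSE)
  wavelength <- wavelength_grid(wavelength)
  if (dim(data)[3] != length(wavelength))
    stop("cube has ", dim(data)[3], " bands but the grid has ",
         length(wavelength), call. = FALSE)
  structure(list(data = data, wavelength = wavelength, kind = kind),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d lines x %d samples x %d bands (%.0f-%.0f nm), %s\n",
              d[1], d[2], d[3], min(x$wavelength), max(x$wavelength), x$kind))
  invisible(x)
}

# ENVI numeric type codes supported by this reader
.envi_types <- list(`4` = list(what = "numeric", size = 4L),
                    `12` = list(what = "integer", size = 2L))

parse_envi_header <- function(header_path) {
  txt <- paste(readLines(header_path, warn = FALSE), collapse = "\n")
  if (!grepl("^\\s*ENVI", txt))
    stop("not an ENVI header: ", header_path, call. = FALSE)
  # collapse brace-delimited blocks onto single lines, then key = value
  lines <- strsplit(txt, "\n")[[1]]
  joined <- character(0); buf <- NULL
  for (ln in lines) {
    if (!is.null(buf)) {
      buf <- paste(buf, ln)
      if (grepl("\\}", ln)) { joined <- c(joined, buf); buf <- NULL }
    } else if (grepl("\\{", ln) && !grepl("\\}", ln)) {
      buf <- ln
    } else joined <- c(joined, ln)
  }
  joined <- joined[grepl("=", joined)]
  keys <- tolower(trimws(sub("=.*$", "", joined)))
  vals <- trimws(sub("^[^=]*=", "", joined))
  stats::setNames(as.list(vals), keys)
}

envi_field <- function(hdr, key, required = TRUE) {
  v <- hdr[[key]]
  if (is.null(v) && required)
    stop("ENVI header missing required field '", key, "'", call. = FALSE)
  v
}

#' Read an ENVI-style hyperspectral cube
#'
#' Supports BIL/BIP/BSQ interleaves, little-endian byte order and data types
#' 4 (float32) and 12 (uint16). Wavelengths are taken from the header's
#' `wavelength` block; a header without one is rejected, as is a binary file
#' whose size disagrees with the header dimensions.
#'
#' @param header_path Path to the `.hdr` text header; the binary is the same
#'   path without the `.hdr` extension (or with `.dat` substituted).
#' @return A [hypercube()] with `kind = "raw"`.
#' @export
read_envi_cube <- function(header_path) {
  hdr <- parse_envi_header(header_path)
  lines   <- as.integer(envi_field(hdr, "lines"))
  samples <- as.integer(envi_field(hdr, "samples"))
  bands   <- as.integer(envi_field(hdr, "bands"))
  dtype   <- as.character(as.integer(envi_field(hdr, "data type")))
  interleave <- tolower(envi_field(hdr, "interleave"))
  byte_order <- as.integer(envi_field(hdr, "byte order", required = FALSE) %||% 0L)
  if (byte_order != 0L)
    stop("only little-endian (byte order = 0) ENVI files are supported",
         call. = FALSE)
  wl_raw <- envi_field(hdr, "wavelength", required = FALSE)
  if (is.null(wl_raw))
    stop("ENVI header missing wavelength metadata", call. = FALSE)
  wl <- as.numeric(strsplit(gsub("[{}]", "", wl_raw), ",")[[1]])
  if (length(wl) != bands)
    stop("header lists ", length(wl), " wavelengths for ", bands, " bands",
         call. = FALSE)
  spec <- .envi_types[[dtype]]
  if (is.null(spec))
    stop("unsupported ENVI data type ", dtype,
         " (supported: 4 = float32, 12 = uint16)", call. = FALSE)
  if (!interleave %in% c("bil", "bip", "bsq"))
    stop("unsupported interleave '", interleave, "'", call. = FALSE)

  bin_path <- sub("\\.hdr$", "", header_path)
  if (!file.exists(bin_path)) bin_path <- paste0(bin_path, ".dat")
  if (!file.exists(bin_path))
    stop("binary file for header not found: ", header_path, call. = FALSE)
  n <- lines * samples * bands
  expected_bytes <- n * spec$size
  actual_bytes <- file.info(bin_path)$size
  if (actual_bytes != expected_bytes)
    stop(sprintf(
      "corrupt ENVI file: header implies %d bytes but binary has %d",
      expected_bytes, actual_bytes), call. = FALSE)
  v <- readBin(bin_path, what = spec$what, n = n, size = spec$size,
               signed = spec$size > 2L, endian = "little")
  v <- as.numeric(v)
  arr <- switch(interleave,
    bsq = aperm(array(v, c(samples, lines, bands)), c(2, 1, 3)),
    bil = aperm(array(v, c(samples, bands, lines)), c(3, 1, 2)),
    bip = aperm(array(v, c(bands, samples, lines)), c(3, 2, 1)))
  hypercube(arr, wl, kind = "raw")
}

#' Write an ENVI-style hyperspectral cube
#'
#' @param cube A [hypercube()].
#' @param header_path Output `.hdr` path; the binary is written beside it
#'   (same path without `.hdr`).
#' @param interleave `"bil"`, `"bip"` or `"bsq"`.
#' @param data_type 4 (float32) or 12 (uint16; values are rounded and must
#'   fit in 0..65535).
#' @return `header_path`, invisibly.
#' @export
write_envi_cube <- function(cube, header_path, interleave = c("bil", "bip", "bsq"),
                            data_type = 4L) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  data_type <- as.integer(data_type)
  spec <- .envi_types[[as.character(data_type)]]
  if (is.null(spec))
    stop("unsupported ENVI data type ", data_type, call. = FALSE)
  d <- dim(cube$data)
  perm <- switch(interleave,
    bsq = c(2, 1, 3),  # inverse perms of the read mappings
    bil = c(2, 3, 1),
    bip = c(3, 2, 1))
  v <- as.vector(aperm(cube$data, perm))
  bin_path <- sub("\\.hdr$", "", header_path)
  if (identical(bin_path, header_path)) bin_path <- paste0(header_path, ".dat")
  if (data_type == 12L) {
    v <- as.integer(round(v))
    if (any(v < 0L | v > 65535L))
      stop("values out of uint16 range for data type 12", call. = FALSE)
    writeBin(v, bin_path, size = 2L, endian = "little")
  } else {
    writeBin(as.numeric(v), bin_path, size = 4L, endian = "little")
  }
  hdr <- c(
    "ENVI",
    "description = { mangohsi export }",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("wavelength = { %s }",
            paste(format(cube$wavelength, trim = TRUE, digits = 10),
                  collapse = ", ")))
  writeLines(hdr, header_path)
  invisible(header_path)
}

#' Read / write a region-of-interest mask as a 0/1 CSV grid
#'
#' Masks are `lines x samples` logical matrices; the CSV stores one row per
#' image line with 0/1 entries and no header.
#'
#' @param mask Logical matrix.
#' @param path File path.
#' @return `read_roi_mask` returns a logical matrix; `write_roi_mask` returns
#'   `path` invisibly.
#' @export
write_roi_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  utils::write.table(matrix(as.integer(mask), nrow(mask)), path,
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_mask
#' @export
read_roi_mask <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  mode(m) <- "logical"
  m
}
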