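#' Wavelength grid
#'
#' Validates and returns a spectral axis: a strictly increasing numeric vector
#' of band-centre wavelengths in nanometres. All downstream containers
#' (hypercubes, spectra matrices, single spectra) carry such a grid.
#'
#' @param values Numeric vector of wavelengths in nm, strictly increasing,
#'   within 300--2600 nm, length at least 2.
#' @return The validated numeric vector.
#' @seealso [default_grid()] for the instrument grid used throughout.
#' @export
wavelength_grid <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a wavelength grid needs at least 2 bands", call. = FALSE)
  if (any(!is.finite(values)))
    stop("wavelengths must be finite", call. = FALSE)
  if (any(diff(values) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(values < 300 | values > 2600))
    stop("wavelengths must lie within [300, 2600] nm", call. = FALSE)
  values
}

#' Default instrument wavelength grid
#'
#' 256 evenly spaced bands spanning 900--1700 nm, the grid of the line-scan
#' NIR camera class this package targets (about 3 nm per band).
#'
#' @return Numeric vector of 256 wavelengths in nm.
#' @export
default_grid <- function() {
  wavelength_grid(seq(900, 1700, length.out = 256L))
}

#' Spectra matrix container
#'
#' An `n x p` matrix of spectra on a shared wavelength grid, with sample ids
#' as rownames and `wavelength`, `kind` (`"reflectance_percent"` or
#' `"absorbance"`) and `provenance` (preprocessing tag) attributes.
#'
#' @param values Numeric matrix (samples in rows, bands in columns) or a
#'   single numeric vector (one spectrum).
#' @param wavelength Wavelength grid, one value per column.
#' @param ids Optional character vector of sample ids (defaults to `s1..sn`).
#' @param kind `"absorbance"` or `"reflectance_percent"`.
#' @param provenance Free-text processing tag, e.g. `"raw"`, `"snv"`.
#' @return A `spectra_matrix` object.
#' @export
spectra_matrix <- function(values, wavelength, ids = NULL,
                           kind = c("absorbance", "reflectance_percent"),
                           provenance = "raw") {
  kind <- match.arg(kind)
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  values <- as.matrix(values)
  wavelength <- wavelength_grid(wavelength)
  if (ncol(values) != length(wavelength))
    stop("spectra have ", ncol(values), " bands but the grid has ",
         length(wavelength), call. = FALSE)
  if (any(!is.finite(values)))
    stop("spectra matrix contains non-finite values", call. = FALSE)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(values)))
  if (length(ids) != nrow(values))
    stop("ids length does not match number of spectra", call. = FALSE)
  rownames(values) <- as.character(ids)
  colnames(values) <- NULL
  structure(values,
            wavelength = wavelength, kind = kind, provenance = provenance,
            class = c("spectra_matrix", "matrix", "array"))
}

#' @export
print.spectra_matrix <- function(x, ...) {
  wl <- attr(x, "wavelength")
  cat(sprintf("<spectra_matrix> %d spectra x %d bands (%.0f-%.0f nm), %s [%s]\n",
              nrow(x), ncol(x), min(wl), max(wl),
              attr(x, "kind"), attr(x, "provenance")))
  invisible(x)
}

#' @export
`[.spectra_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = FALSE)
  wl <- attr(x, "wavelength")
  if (!missing(j)) wl <- wl[j]
  structure(out, wavelength = wl, kind = attr(x, "kind"),
            provenance = attr(x, "provenance"),
            ground_truth = attr(x, "ground_truth"),
            class = class(x))
}

# re-wrap a plain matrix in the metadata of a template spectra_matrix
rewrap_spectra <- function(values, template, provenance = NULL) {
  structure(values,
            wavelength = attr(template, "wavelength"),
            kind = attr(template, "kind"),
            provenance = provenance %||% attr(template, "provenance"),
            ground_truth = attr(template, "ground_truth"),
            class = c("spectra_matrix", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wavelengths of a spectral object
#'
#' @param x A `spectra_matrix`, `nir_spectrum` or `hypercube`.
#' @return Numeric vector of wavelengths in nm.
#' @export
wavelengths <- function(x) {
  wl <- if (is.list(x)) x$wavelength else attr(x, "wavelength")
  if (is.null(wl)) stop("object carries no wavelength grid", call. = FALSE)
  wl
}

#' Single spectrum
#'
#' @param sample_id Identifier carried along reports.
#' @param wavelength Wavelength grid.
#' @param values Per-band values, same length as the grid, all finite.
#' @param kind `"absorbance"` or `"reflectance_percent"`.
#' @return An `nir_spectrum` object (list with the above fields).
#' @export
nir_spectrum <- function(sample_id, wavelength, values,
                         kind = c("absorbance", "reflectance_percent")) {
  kind <- match.arg(kind)
  wavelength <- wavelength_grid(wavelength)
  values <- as.numeric(values)
  if (length(values) != length(wavelength))
    stop("spectrum length does not match grid", call. = FALSE)
  if (any(!is.finite(values)))
    stop("spectrum contains non-finite values", call. = FALSE)
  structure(list(sample_id = as.character(sample_id),
                 wavelength = wavelength, values = values, kind = kind),
            class = "nir_spectrum")
}

#' @export
print.nir_spectrum <- function(x, ...) {
  cat(sprintf("<nir_spectrum> %s: %d bands (%.0f-%.0f nm), %s\n",
              x$sample_id, length(x$values), min(x$wavelength),
              max(x$wavelength), x$kind))
  invisible(x)
}

#' Write / read spectra as CSV with a wavelength header
#'
#' The portable exchange format for spectra: first column `id`, remaining
#' columns named by wavelength (nm). `kind` and `provenance` are stored in a
#' `# kind: ... provenance: ...` comment on the first line.
#'
#' @param x A `spectra_matrix`.
#' @param path File path.
#' @return `write_spectra` returns `path` invisibly; `read_spectra` returns a
#'   `spectra_matrix`.
#' @export
write_spectra <- function(x, path) {
  stopifnot(inherits(x, "spectra_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind: %s provenance: %s",
                     attr(x, "kind"), attr(x, "provenance")), con)
  df <- data.frame(id = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE)
  names(df) <- c("id", format(attr(x, "wavelength"), trim = TRUE, digits = 10))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  first <- readLines(path, n = 1L)
  kind <- "absorbance"; prov <- "raw"
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    m <- regmatches(first, regexec("kind: *(\\S+) +provenance: *(\\S+)", first))[[1]]
    if (length(m) == 3L) { kind <- m[2]; prov <- m[3] }
  }
  df <- utils::read.csv(path, skip = skip, check.names = FALSE)
  wl <- as.numeric(names(df)[-1])
  spectra_matrix(as.matrix(df[, -1, drop = FALSE]), wl, ids = df$id,
                 kind = kind, provenance = prov)
}
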