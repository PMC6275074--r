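#' White/dark reference frames
#'
#' Pairs the white-board scan `W` and the closed-shutter dark frame `B` used
#' for reflectance calibration. References may be full cubes
#' (`lines x samples x bands`) or per-line frames (`samples x bands`), the
#' usual case for a line-scan camera: a 2-D reference is broadcast across all
#' lines of the raw cube.
#'
#' @param white White reference, 2-D or 3-D numeric array.
#' @param dark Dark reference with the same shape as `white`.
#' @return A `reference_frames` object.
#' @export
reference_frames <- function(white, dark) {
  if (!identical(dim(white), dim(dark)))
    stop("white and dark references must share a shape", call. = FALSE)
  nd <- length(dim(white))
  if (!nd %in% c(2L, 3L))
    stop("references must be 2-D (samples x bands) or 3-D cubes", call. = FALSE)
  structure(list(white = white, dark = dark), class = "reference_frames")
}

broadcast_ref <- function(ref, d) {
  if (length(dim(ref)) == 3L) {
    if (!identical(dim(ref), d))
      stop("reference cube shape does not match raw cube", call. = FALSE)
    return(ref)
  }
  if (!identical(dim(ref), d[2:3]))
    stop("per-line reference must be samples x bands", call. = FALSE)
  array(rep(as.vector(ref), each = d[1]), dim = d)
}

#' Dark/white reflectance calibration
#'
#' Converts raw digital numbers to percent reflectance pixel- and band-wise:
#' `R = (I0 - B) / (W - B) * 100`. Pixels where the denominator `W - B` is
#' not larger than `eps` (dead or saturated sensor elements) are set to `NA`
#' and counted in the `masked_pixels` attribute; ROI averaging skips them.
#'
#' @param raw A [hypercube()] with `kind = "raw"`.
#' @param refs A [reference_frames()] object.
#' @param eps Division guard in raw-count units (default `1e-6`).
#' @return A [hypercube()] with `kind = "reflectance_percent"`.
#' @export
calibrate_reflectance <- function(raw, refs, eps = 1e-6) {
  stopifnot(inherits(raw, "hypercube"), inherits(refs, "reference_frames"))
  if (raw$kind != "raw")
    stop("calibrate_reflectance expects a raw cube, got kind '", raw$kind, "'",
         call. = FALSE)
  d <- dim(raw$data)
  W <- broadcast_ref(refs$white, d)
  B <- broadcast_ref(refs$dark, d)
  denom <- W - B
  bad <- denom <= eps
  denom[bad] <- NA_real_
  refl <- (raw$data - B) / denom * 100
  out <- hypercube(refl, raw$wavelength, kind = "raw")
  out$kind <- "reflectance_percent"
  attr(out, "masked_pixels") <- sum(bad)
  out
}

#' Reflectance / absorbance conversion
#'
#' `reflectance_to_absorbance` applies the log(1/R) transform,
#' `A = log10(100 / R%)`; `absorbance_to_reflectance` inverts it,
#' `R% = 100 * 10^-A`. Non-positive reflectance values cannot be transformed
#' and become `NA` with a warning reporting their count. Works on hypercubes,
#' spectra matrices, single spectra and bare numeric arrays.
#'
#' @param x Percent-reflectance object.
#' @return Object of the same shape in absorbance units (and vice versa).
#' @export
reflectance_to_absorbance <- function(x) {
  if (inherits(x, "hypercube")) {
    if (x$kind != "reflectance_percent")
      stop("cube is not in percent reflectance", call. = FALSE)
    x$data <- .to_absorbance(x$data)
    x$kind <- "absorbance"
    return(x)
  }
  if (inherits(x, "spectra_matrix")) {
    if (attr(x, "kind") != "reflectance_percent")
      stop("spectra are not in percent reflectance", call. = FALSE)
    out <- rewrap_spectra(.to_absorbance(unclass(x)), x)
    attr(out, "kind") <- "absorbance"
    return(out)
  }
  if (inherits(x, "nir_spectrum")) {
    if (x$kind != "reflectance_percent")
      stop("spectrum is not in percent reflectance", call. = FALSE)
    x$values <- .to_absorbance(x$values)
    x$kind <- "absorbance"
    return(x)
  }
  .to_absorbance(x)
}

.to_absorbance <- function(v) {
  bad <- !is.na(v) & v <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive reflectance value(s) masked as NA",
            call. = FALSE)
    v[bad] <- NA_real_
  }
  log10(100 / v)
}

#' @rdname reflectance_to_absorbance
#' @export
absorbance_to_reflectance <- function(x) {
  if (inherits(x, "hypercube")) {
    if (x$kind != "absorbance") stop("cube is not in absorbance", call. = FALSE)
    x$data <- 100 * 10^(-x$data)
    x$kind <- "reflectance_percent"
    return(x)
  }
  if (inherits(x, "spectra_matrix")) {
    if (attr(x, "kind") != "absorbance")
      stop("spectra are not in absorbance", call. = FALSE)
    out <- rewrap_spectra(100 * 10^(-unclass(x)), x)
    attr(out, "kind") <- "reflectance_percent"
    return(out)
  }
  if (inherits(x, "nir_spectrum")) {
    if (x$kind != "absorbance") stop("spectrum is not in absorbance", call. = FALSE)
    x$values <- 100 * 10^(-x$values)
    x$kind <- "reflectance_percent"
    return(x)
  }
  100 * 10^(-x)
}

#' Mean spectrum over a region of interest
#'
#' Per-band arithmetic mean over the pixels flagged `TRUE` in the mask
#' (typically the bruised area, or any patch on a control fruit). Pixels
#' masked `NA` by calibration are excluded band-wise.
#'
#' @param cube Calibrated [hypercube()] (reflectance or absorbance).
#' @param mask Logical `lines x samples` matrix with at least one `TRUE`.
#' @param label Mask label appended to the sample id (default `"roi"`).
#' @param id Cube/fruit identifier (default `"cube"`).
#' @return An [nir_spectrum()].
#' @export
extract_roi_mean <- function(cube, mask, label = "roi", id = "cube") {
  stopifnot(inherits(cube, "hypercube"))
  if (cube$kind == "raw")
    stop("extract_roi_mean expects a calibrated cube", call. = FALSE)
  d <- dim(cube$data)
  if (!is.matrix(mask) || !identical(dim(mask), d[1:2]))
    stop("mask must be a lines x samples logical matrix", call. = FALSE)
  idx <- which(mask)
  if (length(idx) == 0L)
    stop("ROI mask selects no pixels", call. = FALSE)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  vals <- colMeans(flat[idx, , drop = FALSE], na.rm = TRUE)
  if (any(!is.finite(vals)))
    stop("ROI mean undefined for some bands (all pixels masked)", call. = FALSE)
  nir_spectrum(paste(id, label, sep = "_"), cube$wavelength, vals,
               kind = cube$kind)
}
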