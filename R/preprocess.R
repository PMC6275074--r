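#' Savitzky-Golay smoothing
#'
#' Moving-window local polynomial least-squares smoothing, applied to each
#' spectrum independently. Interior points use the classical Savitzky-Golay
#' convolution kernel; the first and last half-windows are smoothed by
#' evaluating the polynomial fitted to the leading/trailing full window
#' (mirror-free edge handling).
#'
#' @param spectra A [spectra_matrix()].
#' @param window Odd window length, at least 3 and smaller than the number of
#'   bands (default 11).
#' @param polyorder Polynomial order, smaller than `window` (default 2).
#' @return A smoothed `spectra_matrix` with provenance `"sg"`.
#' @export
savitzky_golay <- function(spectra, window = 11L, polyorder = 2L) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3", call. = FALSE)
  if (polyorder >= window)
    stop("polyorder must be smaller than window", call. = FALSE)
  if (window >= ncol(spectra))
    stop("window must be smaller than the number of bands", call. = FALSE)
  filt <- signal::sgolay(p = polyorder, n = window)
  out <- t(apply(unclass(spectra), 1L,
                 function(x) signal::sgolayfilt(x, filt)))
  rownames(out) <- rownames(spectra)
  rewrap_spectra(out, spectra, provenance = "sg")
}

#' Standard normal variate transform
#'
#' Centres and scales each spectrum to zero mean and unit standard deviation
#' (sample convention, `n - 1` denominator), removing additive offsets and
#' multiplicative scatter differences between samples.
#'
#' @param spectra A [spectra_matrix()].
#' @return A `spectra_matrix` with provenance `"snv"`.
#' @export
snv <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  x <- unclass(spectra)
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  zero <- sdv == 0
  if (any(zero))
    stop("constant spectrum cannot be SNV-scaled: ",
         paste(rownames(x)[zero], collapse = ", "), call. = FALSE)
  out <- (x - mu) / sdv
  rewrap_spectra(out, spectra, provenance = "snv")
}

#' Multiplicative scatter correction: fit the reference
#'
#' The MSC reference is the column-wise mean of the fitting (calibration)
#' spectra, frozen at fit time and reused unchanged for validation and
#' prediction spectra so no information leaks across the split.
#'
#' @param training A [spectra_matrix()] with at least 2 spectra.
#' @return An `msc_reference` object.
#' @export
msc_fit <- function(training) {
  stopifnot(inherits(training, "spectra_matrix"))
  if (nrow(training) < 2L)
    stop("MSC reference needs at least 2 training spectra", call. = FALSE)
  structure(list(reference = colMeans(unclass(training)),
                 wavelength = attr(training, "wavelength")),
            class = "msc_reference")
}

#' Multiplicative scatter correction: apply
#'
#' Each spectrum `x` is regressed on the reference, `x ~ a + b * ref`, by
#' ordinary least squares over bands, and corrected as `(x - a) / b`. The
#' fitted intercepts and slopes are kept in the `msc_coefficients` attribute
#' for audit.
#'
#' @param spectra A [spectra_matrix()] on the reference's grid.
#' @param ref An `msc_reference` from [msc_fit()].
#' @return A corrected `spectra_matrix` with provenance `"msc"`.
#' @export
msc_apply <- function(spectra, ref) {
  stopifnot(inherits(spectra, "spectra_matrix"), inherits(ref, "msc_reference"))
  if (!isTRUE(all.equal(attr(spectra, "wavelength"), ref$wavelength)))
    stop("spectra grid does not match the MSC reference grid", call. = FALSE)
  r <- ref$reference
  rc <- r - mean(r)
  vr <- sum(rc^2)
  if (vr == 0) stop("degenerate MSC reference (constant)", call. = FALSE)
  x <- unclass(spectra)
  xc <- x - rowMeans(x)
  b <- as.vector(xc %*% rc) / vr
  a <- rowMeans(x) - b * mean(ref$reference)
  if (any(abs(b) < 1e-8))
    stop("degenerate MSC fit (|slope| < 1e-8) for: ",
         paste(rownames(x)[abs(b) < 1e-8], collapse = ", "), call. = FALSE)
  out <- (x - a) / b
  out <- rewrap_spectra(out, spectra, provenance = "msc")
  attr(out, "msc_coefficients") <- data.frame(id = rownames(x),
                                              intercept = a, slope = b)
  out
}

#' Apply a named preprocessing method
#'
#' Dispatcher used by the pipeline config: `"snv"`, `"sg"`, `"msc"` or
#' `"none"`. For `"msc"` the reference is fitted on the rows listed in
#' `fit_rows` (the calibration set) and applied to all spectra.
#'
#' @param spectra A [spectra_matrix()].
#' @param method Method name.
#' @param fit_rows Row indices used to fit the MSC reference (default: all).
#' @param sg_window,sg_polyorder Savitzky-Golay parameters.
#' @return A preprocessed `spectra_matrix`.
#' @export
preprocess_spectra <- function(spectra, method = c("snv", "sg", "msc", "none"),
                               fit_rows = seq_len(nrow(spectra)),
                               sg_window = 11L, sg_polyorder = 2L) {
  method <- match.arg(method)
  switch(method,
    none = spectra,
    snv = snv(spectra),
    sg = savitzky_golay(spectra, sg_window, sg_polyorder),
    msc = msc_apply(spectra, msc_fit(spectra[fit_rows, , drop = FALSE])))
}
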