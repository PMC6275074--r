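# Small in-code fixtures shared across test files.

# tiny deterministic cube: values distinct per (line, sample, band)
tiny_cube <- function(lines = 4L, samples = 3L, bands = 8L) {
  wl <- seq(1000, 1400, length.out = bands)
  arr <- array(0, c(lines, samples, bands))
  for (l in seq_len(lines)) for (s in seq_len(samples)) for (b in seq_len(bands))
    arr[l, s, b] <- 100 * l + 10 * s + b
  hypercube(arr, wl, kind = "raw")
}

# random spectra matrix on a small grid
random_spectra <- function(n = 6L, p = 20L, seed = 1L) {
  set.seed(seed)
  wl <- seq(900, 1700, length.out = p)
  spectra_matrix(matrix(rnorm(n * p, 0.5, 0.1), n, p), wl)
}

# direct least-squares Savitzky-Golay oracle: fit a polynomial of the given
# order to the window centred on each interior point, evaluate at the centre
sg_oracle <- function(x, window, polyorder) {
  h <- (window - 1L) / 2L
  n <- length(x)
  out <- x
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    if (i - lo < h) { lo <- 1L; hi <- window }
    if (hi - i < h) { hi <- n; lo <- n - window + 1L }
    t_ <- (lo:hi) - i
    fit <- stats::lm.fit(outer(t_, 0:polyorder, `^`), x[lo:hi])
    out[i] <- fit$coefficients[1]
  }
  out
}
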