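test_that("ENVI write/read round-trips bit-exactly for every interleave", {
  cube <- tiny_cube(4L, 3L, 8L)
  for (il in c("bil", "bip", "bsq")) {
    hdr <- file.path(withr::local_tempdir(), paste0("cube_", il, ".hdr"))
    write_envi_cube(cube, hdr, interleave = il)
    back <- read_envi_cube(hdr)
    expect_identical(back$data, cube$data, label = paste("interleave", il))
    expect_equal(back$wavelength, cube$wavelength)
  }
})

test_that("uint16 cubes round-trip exactly for integer-valued data", {
  cube <- tiny_cube()
  hdr <- file.path(withr::local_tempdir(), "u16.hdr")
  write_envi_cube(cube, hdr, interleave = "bsq", data_type = 12L)
  expect_identical(read_envi_cube(hdr)$data, cube$data)
})

test_that("interleave encodings agree with direct index arithmetic", {
  # independent oracle: compute the on-disk value stream from first principles
  cube <- tiny_cube(3L, 4L, 5L)
  d <- dim(cube$data)
  oracle <- list(
    bsq = as.vector(vapply(seq_len(d[3]), function(b)
      as.vector(t(cube$data[, , b])), numeric(d[1] * d[2]))),
    bil = unlist(lapply(seq_len(d[1]), function(l)
      as.vector(cube$data[l, , ]))),
    bip = unlist(lapply(seq_len(d[1]), function(l)
      as.vector(t(cube$data[l, , ])))))
  for (il in names(oracle)) {
    hdr <- file.path(withr::local_tempdir(), paste0(il, ".hdr"))
    write_envi_cube(cube, hdr, interleave = il)
    raw <- readBin(sub("\\.hdr$", "", hdr), "numeric", size = 4L,
                   n = prod(d), endian = "little")
    expect_equal(raw, oracle[[il]], tolerance = 1e-6, label = il)
    expect_identical(read_envi_cube(hdr)$data, cube$data)
  }
})

test_that("corrupt or incomplete ENVI files are rejected", {
  cube <- tiny_cube()
  dir <- withr::local_tempdir()
  hdr <- file.path(dir, "c.hdr")
  write_envi_cube(cube, hdr)
  # truncate the binary by one band worth of data
  bin <- sub("\\.hdr$", "", hdr)
  bytes <- readBin(bin, "raw", n = file.info(bin)$size)
  writeBin(bytes[seq_len(length(bytes) - 4L)], bin)
  expect_error(read_envi_cube(hdr), "corrupt")
  # header without wavelengths
  txt <- readLines(file.path(dir, "c.hdr"))
  writeLines(txt[!grepl("wavelength", txt)], file.path(dir, "c.hdr"))
  expect_error(suppressWarnings(read_envi_cube(file.path(dir, "c.hdr"))),
               "wavelength")
})

test_that("calibration maps white to 100, dark to 0 and the midpoint to 50", {
  set.seed(3)
  d <- c(5L, 4L, 6L)
  wl <- seq(900, 1700, length.out = d[3])
  W <- array(runif(prod(d), 2000, 4000), d)
  B <- array(runif(prod(d), 50, 150), d)
  refs <- reference_frames(W, B)
  to_cube <- function(a) hypercube(a, wl, kind = "raw")
  expect_equal(calibrate_reflectance(to_cube(W), refs)$data,
               array(100, d))
  expect_equal(calibrate_reflectance(to_cube(B), refs)$data,
               array(0, d))
  expect_equal(calibrate_reflectance(to_cube((W + B) / 2), refs)$data,
               array(50, d))
})

test_that("per-line 2-D references broadcast across lines", {
  d <- c(6L, 3L, 4L)
  wl <- seq(900, 1700, length.out = d[3])
  W2 <- matrix(runif(d[2] * d[3], 2000, 4000), d[2], d[3])
  B2 <- matrix(100, d[2], d[3])
  raw <- hypercube(array(rep(as.vector((W2 + B2) / 2), each = d[1]), d), wl)
  out <- calibrate_reflectance(raw, reference_frames(W2, B2))
  expect_equal(out$data, array(50, d))
})

test_that("dead pixels (W - B <= eps) are masked and counted", {
  d <- c(2L, 2L, 3L)
  wl <- c(1000, 1100, 1200)
  W <- array(1000, d); B <- array(100, d)
  W[1, 1, 2] <- B[1, 1, 2]  # dead element
  raw <- hypercube(array(500, d), wl)
  out <- calibrate_reflectance(raw, reference_frames(W, B))
  expect_true(is.na(out$data[1, 1, 2]))
  expect_identical(attr(out, "masked_pixels"), 1L)
})

test_that("absorbance transform matches log10(100/R) anchor points", {
  expect_equal(reflectance_to_absorbance(100), 0)
  expect_equal(reflectance_to_absorbance(10), 1)
  expect_equal(reflectance_to_absorbance(1), 2)
  expect_warning(out <- reflectance_to_absorbance(c(50, -1, 0)),
                 "2 non-positive")
  expect_true(all(is.na(out[2:3])))
})

test_that("reflectance/absorbance conversion is a bijection on (0, Inf)", {
  set.seed(7)
  r <- 10^runif(200, -3, 2.3)  # 0.001 .. ~200 percent
  back <- absorbance_to_reflectance(reflectance_to_absorbance(r))
  expect_equal(back, r, tolerance = 1e-10)
  # container round-trip keeps kind flags coherent
  sm <- random_spectra()
  attr(sm, "kind") <- "reflectance_percent"
  sm2 <- absorbance_to_reflectance(reflectance_to_absorbance(sm))
  expect_equal(unclass(sm2), unclass(sm), tolerance = 1e-10)
  expect_identical(attr(sm2, "kind"), "reflectance_percent")
})

test_that("ROI mean reproduces single pixels, uniform cubes and a hand mean", {
  cube <- tiny_cube(4L, 3L, 8L)
  cube$kind <- "absorbance"
  mask1 <- matrix(FALSE, 4, 3); mask1[2, 3] <- TRUE
  expect_equal(extract_roi_mean(cube, mask1)$values, cube$data[2, 3, ])

  unif <- hypercube(array(0.7, c(4, 3, 8)), cube$wavelength)
  unif$kind <- "absorbance"
  mask <- matrix(c(TRUE, FALSE), 4, 3)
  expect_equal(extract_roi_mean(unif, mask)$values, rep(0.7, 8))

  mask3 <- matrix(FALSE, 4, 3); mask3[cbind(c(1, 3, 4), c(1, 2, 3))] <- TRUE
  oracle <- (cube$data[1, 1, ] + cube$data[3, 2, ] + cube$data[4, 3, ]) / 3
  expect_equal(extract_roi_mean(cube, mask3)$values, oracle)
  expect_error(extract_roi_mean(cube, matrix(FALSE, 4, 3)), "no pixels")
})

test_that("ROI mean ignores pixel order and NA-masked pixels", {
  cube <- tiny_cube(4L, 3L, 8L)
  cube$kind <- "reflectance_percent"
  full <- matrix(TRUE, 4, 3)
  ref <- extract_roi_mean(cube, full)$values
  expect_equal(ref, apply(cube$data, 3, mean))
  cube$data[2, 2, 5] <- NA
  withNA <- extract_roi_mean(cube, full)$values
  expect_equal(withNA[5], mean(cube$data[, , 5], na.rm = TRUE))
  expect_equal(withNA[-5], ref[-5])
})

test_that("ROI masks and spectra CSV round-trip through their text formats", {
  dir <- withr::local_tempdir()
  m <- matrix(runif(12) > 0.5, 4, 3)
  write_roi_mask(m, file.path(dir, "m.csv"))
  expect_identical(read_roi_mask(file.path(dir, "m.csv")), m)
  sm <- random_spectra(n = 4L, p = 10L)
  write_spectra(sm, file.path(dir, "s.csv"))
  back <- read_spectra(file.path(dir, "s.csv"))
  expect_equal(unclass(back), unclass(sm), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(back, "wavelength"), attr(sm, "wavelength"))
  expect_identical(rownames(back), rownames(sm))
})
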