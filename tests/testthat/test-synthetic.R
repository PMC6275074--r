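test_that("group statistics table is complete and monotone with height/day", {
  st <- mango_group_stats()
  expect_identical(nrow(st), 48L)  # 4 attributes x 4 heights x 3 days
  pick <- function(a, h, d) st$mean[st$attribute == a & st$height == h &
                                      st$day == d]
  # firmness and TA fall, TSS and chroma rise with drop height on day 1
  expect_true(all(diff(sapply(c(0.5, 1, 1.5), pick, a = "firmness", d = 1)) < 0))
  expect_true(all(diff(sapply(c(0.5, 1, 1.5), pick, a = "ta", d = 5)) < 0))
  expect_true(all(diff(sapply(c(0.5, 1, 1.5), pick, a = "tss", d = 1)) > 0))
  expect_true(all(diff(sapply(c(1, 3, 5), pick, a = "chroma", h = 0.5)) > 0))
  # controls ripen more slowly than the 0.5 m group
  expect_gt(pick("firmness", 0, 5), pick("firmness", 0.5, 5))
  expect_equal(pick("firmness", 0, 1), pick("firmness", 0.5, 1))
})

test_that("simulated group means match their configured targets (n = 200)", {
  cfg <- sim_config(heights = 0.5, days = 1L, n_fruits = 200L)
  q <- simulate_quality(cfg, seed = 31L)
  # within 2 standard errors of the configured mean 48.79 (sd 7.09)
  expect_lt(abs(mean(q$firmness) - 48.79), 2 * 7.09 / sqrt(200))
  expect_lt(abs(mean(q$ta) - 1.99), 2 * 0.16 / sqrt(200))
  # configured correlations survive the draw
  expect_gt(cor(q$firmness, q$ta), 0.3)
  expect_lt(cor(q$firmness, q$tss), -0.3)
})

test_that("zero-sd configuration pins every fruit at the group mean", {
  st <- mango_group_stats()
  st$sd <- 0
  cfg <- sim_config(heights = 1.0, days = 3L, n_fruits = 5L, stats = st)
  q <- simulate_quality(cfg, seed = 1L)
  expect_equal(q$firmness, rep(37.40, 5))
  expect_equal(q$tss, rep(11.76, 5))
  expect_equal(q$rpi, rep(ripening_index(37.40, 1.40, 11.76), 5))
})

test_that("mean RPI decreases with day and with drop height", {
  cfg <- sim_config(n_fruits = 200L)
  q <- simulate_quality(cfg, seed = 5L)
  m <- function(h, d) mean(q$rpi[q$height == h & q$day == d])
  for (h in c(0.5, 1.0, 1.5))
    expect_true(m(h, 1) > m(h, 3) && m(h, 3) > m(h, 5),
                label = paste("day trend at", h, "m"))
  for (d in c(1, 3, 5))
    expect_gt(m(0.5, d), m(1.5, d))
})

test_that("spectra differ only near the sugar band when only TSS differs", {
  cfg <- sim_config()
  rec <- data.frame(fruit_id = "a", height = 1.0, firmness = 40, tss = 10,
                    ta = 1.5)
  rec2 <- rec; rec2$tss <- 13
  s1 <- simulate_spectrum(rec, cfg, noise = FALSE)
  s2 <- simulate_spectrum(rec2, cfg, noise = FALSE)
  wl <- cfg$grid
  # Gaussian tails: ~1e-3 of the depth change remains at 3 band-widths,
  # numerically negligible (< 1e-9) only beyond ~6.5
  away3 <- abs(wl - 1190) > 3 * cfg$bands$widths["sugar"]
  expect_lt(max(abs(s1$values - s2$values)[away3]), 1e-3)
  away65 <- abs(wl - 1190) > 6.5 * cfg$bands$widths["sugar"]
  expect_lt(max(abs(s1$values - s2$values)[away65]), 1e-9)
  expect_gt(max(abs(s1$values - s2$values)), 0.05)
})

test_that("greater drop height lowers absorbance across 1400-1500 nm", {
  cfg <- sim_config()
  rec <- data.frame(fruit_id = "a", height = 0.5, firmness = 40, tss = 11,
                    ta = 1.5)
  rech <- rec; rech$height <- 1.5
  s_low <- simulate_spectrum(rec, cfg, noise = FALSE)
  s_high <- simulate_spectrum(rech, cfg, noise = FALSE)
  sel <- cfg$grid >= 1400 & cfg$grid <= 1500
  expect_lt(mean(s_high$values[sel]), mean(s_low$values[sel]))
})

test_that("SNV collapses scatter-distorted copies of one latent spectrum", {
  cfg <- sim_config(noise_sd = 0)  # scatter only
  rec <- data.frame(fruit_id = "a", height = 1.0, firmness = 40, tss = 11,
                    ta = 1.5)
  set.seed(41)
  vals <- t(replicate(6, simulate_spectrum(rec, cfg)$values))
  sm <- spectra_matrix(vals, cfg$grid)
  out <- unclass(snv(sm))
  spread <- sqrt(mean(apply(out, 2, var)))
  expect_lt(spread, 1e-10)
})

test_that("datasets are reproducible bit-exactly under a fixed seed", {
  d1 <- simulate_dataset(seed = 77L)
  d2 <- simulate_dataset(seed = 77L)
  expect_identical(d1$quality, d2$quality)
  expect_identical(unclass(d1$spectra), unclass(d2$spectra))
  expect_true(all(is.finite(unclass(d1$spectra))))
  expect_identical(nrow(d1$quality), 240L)
})

test_that("simulated cubes invert to the record spectrum through calibration", {
  cfg <- sim_config()
  rec <- data.frame(fruit_id = "f1", height = 1.5, firmness = 35, tss = 12,
                    ta = 0.8)
  sim <- simulate_cube(rec, cfg, dims = c(16L, 16L), pixel_noise_sd = 0)
  refl <- calibrate_reflectance(sim$cube, sim$refs)
  absb <- reflectance_to_absorbance(refl)
  got <- extract_roi_mean(absb, sim$mask, id = "f1")
  expect_equal(got$values, sim$spectrum$values, tolerance = 1e-8)
  # single-pixel ROI equals that pixel exactly
  one <- matrix(FALSE, 16, 16)
  px <- which(sim$mask, arr.ind = TRUE)[1, ]
  one[px[1], px[2]] <- TRUE
  expect_equal(extract_roi_mean(absb, one)$values, absb$data[px[1], px[2], ])
})

test_that("ROI averaging shrinks pixel noise like 1/sqrt(n)", {
  cfg <- sim_config()
  rec <- data.frame(fruit_id = "f1", height = 1.0, firmness = 40, tss = 11,
                    ta = 1.5)
  s <- 0.8
  rms <- replicate(20, {
    sim <- simulate_cube(rec, cfg, dims = c(20L, 20L), pixel_noise_sd = s)
    refl <- calibrate_reflectance(sim$cube, sim$refs)
    roi <- extract_roi_mean(refl, sim$mask)
    truth <- 100 * 10^(-sim$spectrum$values)
    sqrt(mean((roi$values - truth)^2))
  })
  n_roi <- sum(simulate_cube(rec, cfg, dims = c(20L, 20L))$mask)
  expect_equal(mean(rms), s / sqrt(n_roi), tolerance = 0.3)
})
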