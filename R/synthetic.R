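#' Group-level quality-attribute statistics
#'
#' Mean and standard deviation of pulp firmness (N), total soluble solids
#' (degrees Brix), titratable acidity (% citric acid) and chroma (delta-b*)
#' per drop height (m) and measurement day, for impact-bruised mango. These
#' are the default parameters of the simulator and encode the expected
#' ripening response to impact: firmness and acidity fall, soluble solids
#' and chroma rise, faster for greater drop heights. Control-group (height
#' 0) statistics are not part of the measured table; they are synthesized
#' from the 0.5 m group by shrinking its day trend toward the day-1 state
#' (`control_shrink` of the trend retained), mimicking undamaged fruit that
#' ripens more slowly.
#'
#' @param include_control Add synthetic height-0 control rows (default TRUE).
#' @param control_shrink Fraction of the 0.5 m day trend retained for
#'   controls (default 0.4).
#' @return Long `data.frame` with columns `height`, `day`, `attribute`,
#'   `mean`, `sd`.
#' @export
mango_group_stats <- function(include_control = TRUE, control_shrink = 0.4) {
  h <- rep(c(0.5, 1.0, 1.5), each = 3L)
  d <- rep(c(1L, 3L, 5L), times = 3L)
  base <- rbind(
    data.frame(attribute = "firmness", height = h, day = d,
               mean = c(48.79, 40.85, 35.31, 44.16, 37.40, 30.32,
                        40.51, 35.66, 27.72),
               sd   = c(7.09, 6.42, 5.94, 7.11, 7.31, 5.28,
                        6.19, 6.24, 4.08)),
    data.frame(attribute = "tss", height = h, day = d,
               mean = c(10.05, 11.27, 11.31, 10.54, 11.76, 12.46,
                        11.19, 11.87, 13.20),
               sd   = c(1.01, 1.16, 1.33, 0.51, 1.12, 0.85,
                        0.60, 0.91, 2.11)),
    data.frame(attribute = "ta", height = h, day = d,
               mean = c(1.99, 1.59, 1.26, 1.89, 1.40, 0.94,
                        1.71, 1.12, 0.35),
               sd   = c(0.16, 0.42, 0.15, 0.17, 0.11, 0.19,
                        0.14, 0.18, 0.13)),
    data.frame(attribute = "chroma", height = h, day = d,
               mean = c(38.03, 47.66, 51.71, 46.25, 49.22, 54.52,
                        50.92, 52.24, 56.51),
               sd   = c(9.86, 5.86, 4.00, 8.38, 4.95, 5.01,
                        5.83, 4.45, 2.79)))
  if (include_control) {
    half <- base[base$height == 0.5, ]
    ctrl <- half
    ctrl$height <- 0
    for (attr_ in unique(half$attribute)) {
      rows <- ctrl$attribute == attr_
      day1 <- half$mean[half$attribute == attr_ & half$day == 1L]
      ctrl$mean[rows] <- day1 + control_shrink * (half$mean[rows] - day1)
    }
    base <- rbind(ctrl, base)
  }
  base[order(base$attribute, base$height, base$day),
       c("height", "day", "attribute", "mean", "sd")]
}

#' Simulation configuration
#'
#' Defines the drop-test study design the simulator emulates: per
#' (drop height, day) group sizes, attribute means/SDs, the spectral band
#' model, attribute-to-band-depth coefficients, scatter and noise levels.
#' The spectral model writes each latent absorbance spectrum as a sloped
#' baseline plus Gaussian absorption bands: water at 970 and 1450 nm and a
#' starch/sugar band at 1190 nm (the water bands at 1950/2250 nm fall
#' outside the 900-1700 nm instrument range and are omitted). Water-band
#' depths decrease with drop height (bruised tissue absorbs less), the
#' 1190 nm depth is affine in TSS, the 1450 nm depth gains an affine TA
#' term, and the baseline slope is affine in firmness. Each measured
#' spectrum is then distorted multiplicatively (slope ~ N(1, `slope_sd`),
#' offset ~ N(0, `offset_sd`)) and with additive band noise.
#'
#' @param heights Drop heights in metres; 0 denotes the undropped control.
#' @param days Measurement days.
#' @param n_fruits Fruits per (height, day) group (default 20).
#' @param stats Attribute statistics table from [mango_group_stats()].
#' @param correlations Named attribute correlations; defaults encode
#'   ripening physiology (firmer fruit keeps more acid, has less sugar).
#' @param grid Wavelength grid (default [default_grid()]).
#' @param noise_sd Additive absorbance noise per band (default 0.003 AU).
#' @param slope_sd,offset_sd Multiplicative scatter model (defaults 0.04 and
#'   0.02 AU).
#' @param firmness_units `"N"` or `"g"`; metadata only, never converted.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(heights = c(0, 0.5, 1.0, 1.5), days = c(1L, 3L, 5L),
                       n_fruits = 20L,
                       stats = mango_group_stats(),
                       correlations = c(firmness_ta = 0.5,
                                        firmness_tss = -0.5),
                       grid = default_grid(),
                       noise_sd = 0.003, slope_sd = 0.04, offset_sd = 0.02,
                       firmness_units = "N") {
  if (n_fruits < 1L) stop("n_fruits must be >= 1", call. = FALSE)
  if (any(c(noise_sd, slope_sd, offset_sd) < 0))
    stop("noise and scatter sds must be >= 0", call. = FALSE)
  grid <- wavelength_grid(grid)
  bands <- list(centers = c(water1 = 970, sugar = 1190, water2 = 1450),
                widths  = c(water1 = 35, sugar = 30, water2 = 50))
  if (any(bands$centers < min(grid) | bands$centers > max(grid)))
    stop("band centers must lie inside the wavelength grid", call. = FALSE)
  for (h in heights) for (d in days) {
    key <- stats$height == h & stats$day == d
    if (sum(key) != 4L)
      stop("stats table lacks a complete (height ", h, ", day ", d, ") entry",
           call. = FALSE)
  }
  structure(list(
    heights = heights, days = days, n_fruits = as.integer(n_fruits),
    stats = stats, correlations = correlations, grid = grid,
    bands = bands,
    # attribute -> spectrum coefficients (absorbance units)
    coefs = list(
      baseline_level = 0.40,
      baseline_slope = function(firmness) 0.05 + 0.002 * (firmness - 38),
      depth_water1 = function(height) 0.25 - 0.04 * height,
      depth_sugar  = function(tss) 0.12 + 0.025 * (tss - 11),
      depth_water2 = function(height, ta) 0.45 - 0.05 * height +
                                          0.08 * (ta - 1.3)),
    noise_sd = noise_sd, slope_sd = slope_sd, offset_sd = offset_sd,
    firmness_units = firmness_units),
    class = "sim_config")
}

attr_cov <- function(sds, correlations) {
  R <- diag(4)
  dimnames(R) <- list(c("firmness", "tss", "ta", "chroma"),
                      c("firmness", "tss", "ta", "chroma"))
  for (nm in names(correlations)) {
    pair <- strsplit(nm, "_", fixed = TRUE)[[1]]
    R[pair[1], pair[2]] <- R[pair[2], pair[1]] <- correlations[[nm]]
  }
  diag(sds) %*% R %*% diag(sds)
}

#' Simulate per-fruit quality records
#'
#' Per (height, day) group, draws the four attributes jointly from a
#' multivariate normal with the configured means/SDs and correlations,
#' truncated at physical bounds (firmness and TSS positive, TA at least
#' 0.05%), then derives each fruit's ripening index via
#' [ripening_index()] and its damage class via [damage_class()] (control
#' fruits are labelled `"control"`).
#'
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed.
#' @return `data.frame` with `fruit_id`, `height`, `day`, `firmness`, `tss`,
#'   `ta`, `chroma`, `rpi`, `damage_class`.
#' @export
simulate_quality <- function(cfg = sim_config(), seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- list()
  for (h in cfg$heights) for (d in cfg$days) {
    key <- cfg$stats$height == h & cfg$stats$day == d
    st <- cfg$stats[key, ]
    mu <- stats::setNames(st$mean, st$attribute)[c("firmness", "tss", "ta",
                                                   "chroma")]
    sds <- stats::setNames(st$sd, st$attribute)[c("firmness", "tss", "ta",
                                                  "chroma")]
    S <- attr_cov(sds, cfg$correlations)
    draws <- MASS::mvrnorm(cfg$n_fruits, mu, S)
    draws <- matrix(draws, ncol = 4L,
                    dimnames = list(NULL, c("firmness", "tss", "ta", "chroma")))
    draws[, "firmness"] <- pmax(draws[, "firmness"], 0.5)
    draws[, "tss"] <- pmax(draws[, "tss"], 0.5)
    draws[, "ta"] <- pmax(draws[, "ta"], 0.05)
    rpi <- ripening_index(draws[, "firmness"], draws[, "ta"], draws[, "tss"])
    cls <- if (h == 0) rep("control", cfg$n_fruits)
           else as.character(damage_class(rpi))
    out[[length(out) + 1L]] <- data.frame(
      fruit_id = sprintf("H%.1f_D%d_%02d", h, d, seq_len(cfg$n_fruits)),
      height = h, day = d,
      firmness = draws[, "firmness"], tss = draws[, "tss"],
      ta = draws[, "ta"], chroma = draws[, "chroma"],
      rpi = rpi, damage_class = cls)
  }
  do.call(rbind, out)
}

# deterministic latent absorbance spectrum of one fruit
latent_spectrum <- function(height, firmness, tss, ta, cfg) {
  wl <- cfg$grid
  x <- (wl - 1300) / 400
  g <- function(center, width) exp(-0.5 * ((wl - center) / width)^2)
  cf <- cfg$coefs
  cf$baseline_level + cf$baseline_slope(firmness) * x +
    cf$depth_water1(height) * g(cfg$bands$centers["water1"],
                                cfg$bands$widths["water1"]) +
    cf$depth_sugar(tss)     * g(cfg$bands$centers["sugar"],
                                cfg$bands$widths["sugar"]) +
    cf$depth_water2(height, ta) * g(cfg$bands$centers["water2"],
                                    cfg$bands$widths["water2"])
}

#' Simulate the NIR spectrum of one fruit
#'
#' Builds the fruit's latent absorbance spectrum from its quality record and
#' (unless `noise = FALSE`) applies the multiplicative scatter distortion and
#' additive band noise of the config.
#'
#' @param record One-row quality record (as from [simulate_quality()]).
#' @param cfg A [sim_config()].
#' @param noise Apply scatter and noise? Default TRUE (uses the current RNG
#'   state).
#' @return An [nir_spectrum()] in absorbance.
#' @export
simulate_spectrum <- function(record, cfg = sim_config(), noise = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  s <- latent_spectrum(record$height, record$firmness, record$tss,
                       record$ta, cfg)
  if (noise) {
    beta <- stats::rnorm(1, 1, cfg$slope_sd)
    alpha <- stats::rnorm(1, 0, cfg$offset_sd)
    s <- alpha + beta * s + stats::rnorm(length(s), 0, cfg$noise_sd)
  }
  nir_spectrum(record$fruit_id, cfg$grid, s, kind = "absorbance")
}

#' Simulate spectra for a set of quality records
#'
#' @param records Quality records from [simulate_quality()].
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed.
#' @return A [spectra_matrix()] (absorbance) with one row per record; the
#'   `ground_truth` attribute stores the planted band centers/widths for
#'   recovery tests.
#' @export
simulate_spectra <- function(records, cfg = sim_config(), seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  vals <- t(vapply(seq_len(nrow(records)), function(i)
    simulate_spectrum(records[i, ], cfg)$values,
    numeric(length(cfg$grid))))
  out <- spectra_matrix(vals, cfg$grid, ids = records$fruit_id,
                        kind = "absorbance")
  attr(out, "ground_truth") <- list(band_centers = cfg$bands$centers,
                                    band_widths = cfg$bands$widths)
  out
}

#' Simulate a full synthetic dataset
#'
#' Convenience wrapper: quality records plus their spectra under one seed.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed.
#' @return List with `quality` (data.frame) and `spectra`
#'   ([spectra_matrix()]).
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  quality <- simulate_quality(cfg)
  spectra <- simulate_spectra(quality, cfg)
  list(quality = quality, spectra = spectra, config = cfg)
}

#' Simulate a small raw hypercube with reference frames and ROI mask
#'
#' End-to-end fixture for the imaging stage: an elliptical bruise ROI whose
#' pixels carry noisy copies of the record's spectrum, embedded in a
#' background of undamaged tissue, pushed through an affine instrument model
#' (smooth white frame, constant dark frame) back to raw counts. Calibrating
#' the emitted cube with the emitted frames and averaging over the emitted
#' mask recovers the record's reflectance spectrum up to the pixel noise
#' divided by the square root of the ROI size.
#'
#' @param record One-row quality record.
#' @param cfg A [sim_config()].
#' @param dims `c(lines, samples)` of the cube (default 32 x 32).
#' @param pixel_noise_sd Per-pixel noise in percent-reflectance units
#'   (default 0.5).
#' @param seed Optional integer seed.
#' @return List with `cube` (raw [hypercube()]), `refs`
#'   ([reference_frames()], per-line), `mask` (logical matrix) and
#'   `spectrum` (the latent [nir_spectrum()], absorbance).
#' @export
simulate_cube <- function(record, cfg = sim_config(), dims = c(32L, 32L),
                          pixel_noise_sd = 0.5, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  L <- as.integer(dims[1]); S <- as.integer(dims[2])
  wl <- cfg$grid; B <- length(wl)
  bruise_A <- latent_spectrum(record$height, record$firmness, record$tss,
                              record$ta, cfg)
  bg <- record
  bg$height <- 0  # undamaged surrounding tissue
  bg_A <- latent_spectrum(bg$height, bg$firmness, bg$tss, bg$ta, cfg)
  bruise_R <- 100 * 10^(-bruise_A)
  bg_R <- 100 * 10^(-bg_A)

  li <- matrix(seq_len(L), L, S)
  si <- matrix(seq_len(S), L, S, byrow = TRUE)
  a <- 0.35 * L; b <- 0.3 * S
  mask <- ((li - (L + 1) / 2) / a)^2 + ((si - (S + 1) / 2) / b)^2 <= 1
  if (!any(mask)) stop("ROI ellipse too small for the frame", call. = FALSE)

  white <- outer(1 - 0.1 * ((seq_len(S) - (S + 1) / 2) / (S / 2))^2,
                 2500 + 1500 * exp(-((wl - 1300) / 600)^2))
  dark <- matrix(100, S, B)

  refl <- array(rep(bg_R, each = L * S), dim = c(L, S, B))
  idx <- which(mask)
  for (k in seq_len(B))
    refl[, , k][idx] <- bruise_R[k]
  if (pixel_noise_sd > 0)
    refl <- refl + array(stats::rnorm(L * S * B, 0, pixel_noise_sd),
                         dim = c(L, S, B))
  W3 <- broadcast_ref(white, c(L, S, B))
  D3 <- broadcast_ref(dark, c(L, S, B))
  raw <- D3 + refl / 100 * (W3 - D3)
  list(cube = hypercube(raw, wl, kind = "raw"),
       refs = reference_frames(white, dark),
       mask = mask,
       spectrum = nir_spectrum(record$fruit_id, wl, bruise_A,
                               kind = "absorbance"))
}
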