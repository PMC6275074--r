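#' Default experiment configuration
#'
#' All study-design constants in one nested list: the drop-test design
#' (heights 0/0.5/1.0/1.5 m, days 1/3/5, 20 fruits per group), the 256-band
#' 900--1700 nm instrument grid, SNV as the default preprocessing, the 3/5
#' calibration split and leave-one-out component selection for regression,
#' 50 CARS Monte-Carlo runs, the RPI damage thresholds 5.0/7.0 and the 3/4
#' training split for discriminant analysis. A YAML rendering of the same
#' structure ships in `inst/extdata/default_config.yaml`; [read_config()]
#' merges a user file over these defaults.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    simulation = list(
      heights = c(0, 0.5, 1.0, 1.5), days = c(1L, 3L, 5L), n_fruits = 20L,
      noise_sd = 0.003, slope_sd = 0.04, offset_sd = 0.02,
      firmness_units = "N"),
    data = list(quality_csv = NULL, spectra_csv = NULL),
    preprocessing = list(method = "snv", sg_window = 11L, sg_polyorder = 2L),
    regression = list(attributes = c("firmness", "tss", "ta", "chroma"),
                      split_ratio = 3 / 5, max_components = 10L,
                      mode = "per_group"),
    cars = list(enabled = TRUE, n_runs = 50L, mc_ratio = 0.8, ncomp = 5L),
    classification = list(enabled = TRUE, slight_min = 7.0, serious_max = 5.0,
                          split_ratio = 3 / 4, cars_attribute = "rpi"),
    instrument = list(n_bands = 256L, wl_min = 900, wl_max = 1700))
}

#' Read an experiment configuration from YAML
#'
#' Values present in the file override [default_config()]; everything else
#' keeps its default.
#'
#' @param path Path to a YAML config file.
#' @return Merged configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

config_to_sim <- function(config) {
  ins <- config$instrument
  sim_config(heights = config$simulation$heights,
             days = as.integer(config$simulation$days),
             n_fruits = config$simulation$n_fruits,
             grid = seq(ins$wl_min, ins$wl_max, length.out = ins$n_bands),
             noise_sd = config$simulation$noise_sd,
             slope_sd = config$simulation$slope_sd,
             offset_sd = config$simulation$offset_sd,
             firmness_units = config$simulation$firmness_units)
}

quality_stats_table <- function(quality) {
  attrs <- c("firmness", "tss", "ta", "chroma", "rpi")
  out <- list()
  for (a in attrs) {
    agg_m <- stats::aggregate(quality[[a]],
                              list(height = quality$height, day = quality$day),
                              mean)
    agg_s <- stats::aggregate(quality[[a]],
                              list(height = quality$height, day = quality$day),
                              stats::sd)
    out[[a]] <- data.frame(attribute = a, height = agg_m$height,
                           day = agg_m$day, mean = agg_m$x, sd = agg_s$x)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df[order(df$attribute, df$height, df$day), ]
}

fit_group_model <- function(Xp, y, split_ratio, max_components, cars_cfg) {
  n <- nrow(Xp)
  sp <- split_calibration_validation(n, ratio = split_ratio)
  Xc <- Xp[sp$calibration, , drop = FALSE]
  yc <- y[sp$calibration]
  selected <- seq_len(ncol(Xp))
  if (isTRUE(cars_cfg$enabled)) {
    cr <- cars_run(Xc, yc, n_runs = cars_cfg$n_runs,
                   mc_ratio = cars_cfg$mc_ratio, ncomp = cars_cfg$ncomp)
    selected <- cr$selected
  } else cr <- NULL
  Xsel <- Xc[, selected, drop = FALSE]
  amax <- min(max_components, nrow(Xsel) - 2L, length(selected))
  cv <- loo_cv(Xsel, yc, max_components = amax)
  model <- fit_pls(Xsel, yc, ncomp = cv$ncomp)
  pred <- predict(model, Xp[sp$validation, selected, drop = FALSE])
  met <- regression_metrics(y[sp$validation], pred)
  list(split = sp, cars = cr, cv = cv, model = model, selected = selected,
       metrics = met)
}

#' Run the full damage-evaluation experiment
#'
#' Executes the pipeline stages in order: simulate (or load) quality records
#' and spectra; preprocess; per quality attribute, split
#' calibration/validation, optionally select wavelengths by CARS on the
#' calibration set, pick the PLS component count by leave-one-out
#' cross-validation and evaluate on the held-out validation set; label
#' damaged fruits by ripening index and fit/evaluate Fisher discriminant
#' analysis on the CARS-selected wavelengths. Only calibration/training
#' samples ever reach a fitting routine.
#'
#' All randomness flows from the single `seed` set at entry, so a rerun with
#' the same config and seed reproduces every table exactly.
#'
#' @param config Configuration list (see [default_config()], [read_config()]).
#' @param seed Integer seed for the whole run.
#' @param output_dir Optional directory; when given, the report tables are
#'   written there as CSV files plus a JSON `manifest.json`.
#' @return A `mango_experiment` list: `quality_stats` (per-group mean/SD
#'   table), `regression` (attribute x height x day validation metrics),
#'   `cars` (diagnostics per fitted model), `confusion_train`,
#'   `confusion_test`, and `manifest`.
#' @export
run_experiment <- function(config = default_config(), seed = 1L,
                           output_dir = NULL) {
  set.seed(as.integer(seed))
  cfg <- config_to_sim(config)

  # --- data stage ---------------------------------------------------------
  if (!is.null(config$data$quality_csv)) {
    quality <- utils::read.csv(config$data$quality_csv, comment.char = "#")
    spectra <- read_spectra(config$data$spectra_csv)
  } else {
    ds <- simulate_dataset(cfg)
    quality <- ds$quality
    spectra <- ds$spectra
  }
  stats_tab <- quality_stats_table(quality)

  # --- preprocessing ------------------------------------------------------
  pp <- config$preprocessing
  spectra_pp <- preprocess_spectra(spectra, method = pp$method,
                                   sg_window = pp$sg_window,
                                   sg_polyorder = pp$sg_polyorder)

  # --- regression stage ---------------------------------------------------
  reg_rows <- list(); cars_diag <- list()
  rg <- config$regression
  damaged <- quality$height > 0
  for (a in rg$attributes) {
    if (identical(rg$mode, "per_group")) {
      for (h in setdiff(unique(quality$height), 0)) for (d in unique(quality$day)) {
        rows <- which(quality$height == h & quality$day == d)
        res <- fit_group_model(spectra_pp[rows, , drop = FALSE],
                               quality[[a]][rows], rg$split_ratio,
                               rg$max_components, config$cars)
        reg_rows[[length(reg_rows) + 1L]] <- data.frame(
          attribute = a, height = h, day = d,
          n_cal = length(res$split$calibration),
          n_val = length(res$split$validation),
          n_wavelengths = length(res$selected), ncomp = res$model$ncomp,
          r2 = res$metrics$r2, rmsep = res$metrics$rmse)
        if (!is.null(res$cars)) {
          dg <- report_cars_diagnostics(res$cars)
          dg$model <- sprintf("%s_H%.1f_D%d", a, h, d)
          cars_diag[[length(cars_diag) + 1L]] <- dg
        }
      }
    } else {
      rows <- which(damaged)
      res <- fit_group_model(spectra_pp[rows, , drop = FALSE],
                             quality[[a]][rows], rg$split_ratio,
                             rg$max_components, config$cars)
      reg_rows[[length(reg_rows) + 1L]] <- data.frame(
        attribute = a, height = NA_real_, day = NA_integer_,
        n_cal = length(res$split$calibration),
        n_val = length(res$split$validation),
        n_wavelengths = length(res$selected), ncomp = res$model$ncomp,
        r2 = res$metrics$r2, rmsep = res$metrics$rmse)
      if (!is.null(res$cars)) {
        dg <- report_cars_diagnostics(res$cars)
        dg$model <- paste0(a, "_pooled")
        cars_diag[[length(cars_diag) + 1L]] <- dg
      }
    }
  }
  regression <- do.call(rbind, reg_rows)

  # --- classification stage ----------------------------------------------
  confusion_train <- confusion_test <- NULL
  cl <- config$classification
  if (isTRUE(cl$enabled)) {
    thr <- damage_thresholds(cl$slight_min, cl$serious_max)
    dq <- quality[damaged, ]
    dX <- spectra_pp[damaged, , drop = FALSE]
    labels <- damage_class(dq$rpi, thr)
    sp <- split_train_test(labels, ratio = cl$split_ratio)
    cr <- cars_run(dX[sp$train, , drop = FALSE],
                   dq[[cl$cars_attribute]][sp$train],
                   n_runs = config$cars$n_runs,
                   mc_ratio = config$cars$mc_ratio,
                   ncomp = config$cars$ncomp)
    feats <- dX[, cr$selected, drop = FALSE]
    da <- fit_lda(feats[sp$train, , drop = FALSE], labels[sp$train])
    confusion_train <- confusion(labels[sp$train],
                                 classify(da, feats[sp$train, , drop = FALSE]),
                                 classes = da$classes, split = "training")
    confusion_test <- confusion(labels[sp$test],
                                classify(da, feats[sp$test, , drop = FALSE]),
                                classes = da$classes, split = "testing")
    dg <- report_cars_diagnostics(cr)
    dg$model <- "classifier"
    cars_diag[[length(cars_diag) + 1L]] <- dg
  }

  manifest <- list(
    seed = as.integer(seed),
    config = config,
    package_version = as.character(utils::packageVersion("mangohsi")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    n_samples = nrow(quality))

  result <- structure(list(quality = quality,
                           quality_stats = stats_tab,
                           regression = regression,
                           cars = if (length(cars_diag))
                             do.call(rbind, cars_diag),
                           confusion_train = confusion_train,
                           confusion_test = confusion_test,
                           manifest = manifest),
                      class = "mango_experiment")
  if (!is.null(output_dir)) write_experiment(result, output_dir)
  result
}

#' @export
print.mango_experiment <- function(x, ...) {
  cat("<mango_experiment>\n")
  cat(sprintf("  %d fruits; %d regression models (median validation R2 %.2f)\n",
              x$manifest$n_samples, nrow(x$regression),
              stats::median(x$regression$r2)))
  if (!is.null(x$confusion_test))
    cat(sprintf("  classifier test accuracy %.1f%%\n",
                100 * sum(diag(x$confusion_test$counts)) /
                  sum(x$confusion_test$counts)))
  invisible(x)
}

#' Write an experiment's report bundle to disk
#'
#' @param result A `mango_experiment` from [run_experiment()].
#' @param output_dir Directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_experiment <- function(result, output_dir) {
  stopifnot(inherits(result, "mango_experiment"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$quality_stats,
                   file.path(output_dir, "quality_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(result$regression,
                   file.path(output_dir, "regression_metrics.csv"),
                   row.names = FALSE)
  if (!is.null(result$cars))
    utils::write.csv(result$cars, file.path(output_dir, "cars_diagnostics.csv"),
                     row.names = FALSE)
  if (!is.null(result$confusion_train))
    write_confusion(result$confusion_train,
                    file.path(output_dir, "confusion_training.csv"))
  if (!is.null(result$confusion_test))
    write_confusion(result$confusion_test,
                    file.path(output_dir, "confusion_testing.csv"))
  jsonlite::write_json(result$manifest,
                       file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(output_dir)
}
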