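#' Exponentially decreasing retention ratio
#'
#' The forced-removal schedule of CARS: the fraction of the full variable set
#' retained at Monte-Carlo iteration `i` is `r(i) = a * exp(-k * i)` with `a`
#' and `k` fixed by the boundary conditions `r(1) = 1` (all `p` variables) and
#' `r(N) = 2/p` (two variables at the last iteration).
#'
#' @param i Iteration index (vectorised), `1 <= i <= n_runs`.
#' @param n_runs Total number of Monte-Carlo iterations.
#' @param p Total number of wavelength variables, `p >= 2`.
#' @return Retained fraction(s) in (0, 1].
#' @export
edf_ratio <- function(i, n_runs, p) {
  p <- as.integer(p); n_runs <- as.integer(n_runs)
  if (p < 2L) stop("p must be >= 2", call. = FALSE)
  if (n_runs < 2L) stop("n_runs must be >= 2", call. = FALSE)
  if (any(i < 1 | i > n_runs)) stop("i out of range 1..n_runs", call. = FALSE)
  k <- log(p / 2) / (n_runs - 1)
  a <- exp(k)
  a * exp(-k * i)
}

#' Competitive adaptive reweighted sampling
#'
#' Monte-Carlo wavelength selection wrapped around PLS. Each iteration:
#' (1) draw `mc_ratio` of the calibration samples without replacement;
#' (2) fit a PLS model on the currently retained wavelengths;
#' (3) enforced removal: keep the `ceiling(r(i) * p)` wavelengths with the
#' largest absolute regression coefficients (`r` from [edf_ratio()]);
#' (4) adaptive reweighted sampling: redraw that many variables from the
#' forced survivors without replacement, with probability proportional to
#' `|b|`; variables with a zero coefficient get zero probability and drop
#' out, so the retained count can fall below the schedule only through
#' exactly-zero coefficients;
#' (5) score the surviving subset by leave-one-out RMSECV on the full
#' calibration set. The subset with the smallest RMSECV across iterations is
#' selected.
#'
#' @param X Calibration [spectra_matrix()] (or plain matrix).
#' @param y Calibration response.
#' @param n_runs Monte-Carlo iterations (default 50).
#' @param mc_ratio Fraction of samples drawn per iteration (default 0.8).
#' @param ncomp Components for the internal PLS fits (default 5, capped by
#'   sample count and retained-set size).
#' @param seed Optional integer seed for a fully deterministic run.
#' @return A `cars_result`: per-iteration table (`iterations`), the retained
#'   sets (`retained_sets`), `best_iteration`, `selected` (band indices) and
#'   `selected_wavelengths` (nm, when `X` carries a grid).
#' @export
cars_run <- function(X, y, n_runs = 50L, mc_ratio = 0.8, ncomp = 5L,
                     seed = NULL) {
  wl <- attr(X, "wavelength")
  X <- unclass(as.matrix(X)); storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (p < 2L) stop("CARS needs at least 2 variables", call. = FALSE)
  if (!(mc_ratio > 0 && mc_ratio < 1))
    stop("mc_ratio must be in (0, 1)", call. = FALSE)
  n_runs <- as.integer(n_runs)
  if (n_runs < 2L) stop("n_runs must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))

  n_mc <- max(2L, round(mc_ratio * n))
  retained <- seq_len(p)
  sets <- vector("list", n_runs)
  counts <- integer(n_runs); rmsecv <- rep(NA_real_, n_runs)
  done <- 0L
  for (i in seq_len(n_runs)) {
    if (length(retained) < 2L) {
      warning("retained set collapsed below 2 variables at iteration ", i,
              "; path truncated", call. = FALSE)
      break
    }
    sub <- sample.int(n, n_mc)
    Xs <- X[sub, retained, drop = FALSE]; ys <- y[sub]
    a <- min(ncomp, n_mc - 1L, length(retained))
    fit <- pls1_nipals(sweep(Xs, 2L, colMeans(Xs)), ys - mean(ys), a)
    b <- if (fit$ncomp > 0L) abs(pls1_coef_path(fit)[, fit$ncomp])
         else rep(1, length(retained))
    # enforced removal by the EDF schedule
    keep_n <- min(ceiling(edf_ratio(i, n_runs, p) * p), length(retained))
    ord <- order(b, decreasing = TRUE)
    forced <- ord[seq_len(keep_n)]
    wts <- b[forced]
    # adaptive reweighted sampling: weighted draws without replacement;
    # zero-coefficient variables have zero sampling probability
    if (any(wts > 0)) {
      pos <- sum(wts > 0)
      draws <- forced[sample.int(length(forced), size = min(keep_n, pos),
                                 replace = FALSE, prob = wts)]
      surv <- sort(draws)
    } else surv <- sort(forced)
    retained <- retained[surv]
    sets[[i]] <- retained
    counts[i] <- length(retained)
    a_cv <- min(ncomp, n - 2L, length(retained))
    cv <- loo_cv(X[, retained, drop = FALSE], y, max_components = a_cv)
    rmsecv[i] <- cv$rmsecv[a_cv]
    done <- i
  }
  if (done == 0L) stop("CARS produced no iterations", call. = FALSE)
  best <- which.min(rmsecv[seq_len(done)])
  selected <- sets[[best]]
  structure(list(
    iterations = data.frame(iteration = seq_len(done),
                            n_retained = counts[seq_len(done)],
                            rmsecv = rmsecv[seq_len(done)],
                            best = seq_len(done) == best),
    retained_sets = sets[seq_len(done)],
    best_iteration = best,
    selected = selected,
    selected_wavelengths = if (!is.null(wl)) wl[selected],
    config = list(n_runs = n_runs, mc_ratio = mc_ratio, ncomp = ncomp)),
    class = "cars_result")
}

#' @export
print.cars_result <- function(x, ...) {
  cat(sprintf("<cars_result> %d iterations, best at %d: %d wavelengths (RMSECV %.4g)\n",
              nrow(x$iterations), x$best_iteration, length(x$selected),
              x$iterations$rmsecv[x$best_iteration]))
  invisible(x)
}

#' Per-iteration CARS diagnostics
#'
#' Emits the per-iteration retained-variable count and RMSECV (with the best
#' iteration flagged), the table behind the usual three-panel CARS diagnostic
#' plot (variable count, RMSECV and coefficient paths versus iteration).
#'
#' @param result A `cars_result`.
#' @param path Optional CSV output path.
#' @return The diagnostics `data.frame`, invisibly when `path` is given.
#' @export
report_cars_diagnostics <- function(result, path = NULL) {
  stopifnot(inherits(result, "cars_result"))
  df <- result$iterations
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
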