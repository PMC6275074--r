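# ---- internal NIPALS PLS1 core -------------------------------------------
# Xc, yc already centered. For a single response NIPALS needs no inner
# iteration: per component w = X'y / |X'y|, t = Xw, p = X't/t't, q = y't/t't,
# then deflate X and y. Returns weights, loadings and per-component y
# loadings; stops early (A reduced) when the residual X carries no signal.
pls1_nipals <- function(Xc, yc, ncomp, tol = 1e-12) {
  n <- nrow(Xc); p <- ncol(Xc)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- numeric(ncomp); TT <- matrix(0, n, ncomp)
  a <- 0L
  for (k in seq_len(ncomp)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w * w))
    if (nw < tol) break
    w <- w / nw
    t_ <- Xc %*% w
    tt <- sum(t_ * t_)
    if (tt < tol) break
    p_ <- crossprod(Xc, t_) / tt
    q_ <- sum(yc * t_) / tt
    Xc <- Xc - tcrossprod(t_, p_)
    yc <- yc - q_ * t_
    a <- k
    W[, k] <- w; P[, k] <- p_; Q[k] <- q_; TT[, k] <- t_
  }
  list(W = W[, seq_len(a), drop = FALSE], P = P[, seq_len(a), drop = FALSE],
       Q = Q[seq_len(a)], scores = TT[, seq_len(a), drop = FALSE], ncomp = a)
}

# cumulative coefficient path: p x A matrix, column a = regression vector
# using the first a components. R = W (P'W)^-1 maps loadings to x-space.
pls1_coef_path <- function(fit) {
  A <- fit$ncomp
  R <- fit$W %*% solve(crossprod(fit$P, fit$W))
  B <- matrix(0, nrow(fit$W), A)
  RQ <- sweep(R, 2L, fit$Q, `*`)
  B[, 1L] <- RQ[, 1L]
  if (A > 1L) for (a in 2:A) B[, a] <- B[, a - 1L] + RQ[, a]
  B
}

#' Fit a NIPALS PLS1 regression model
#'
#' Bilinear latent-variable regression of a single response on a spectral
#' matrix: X and y are mean-centred (no autoscaling), components are
#' extracted by NIPALS with deflation after each component, and the compact
#' regression vector `b` is assembled so that
#' `yhat = y_mean + (x - x_mean) %*% b`. The score-space route and the
#' compact route agree to numerical precision (see [predict.pls_model()]).
#'
#' @param X A [spectra_matrix()] or plain numeric matrix (samples x bands).
#' @param y Numeric response, one value per row of `X`.
#' @param ncomp Number of latent components; capped at `min(n - 1, p)` (with
#'   a warning) and reduced further if the centred `X` runs out of rank.
#' @return A `pls_model` with fields `x_mean`, `y_mean`, `weights`,
#'   `x_loadings`, `y_loadings`, `coefficients`, `ncomp`, `wavelength`.
#' @export
fit_pls <- function(X, y, ncomp) {
  wl <- attr(X, "wavelength")
  X <- unclass(as.matrix(X)); storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("PLS needs at least 2 samples", call. = FALSE)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (any(!is.finite(y)) || any(!is.finite(X)))
    stop("X and y must be finite", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("response has zero variance", call. = FALSE)
  ncomp <- as.integer(ncomp)
  amax <- min(n - 1L, p)
  if (ncomp > amax) {
    warning("ncomp reduced from ", ncomp, " to ", amax, call. = FALSE)
    ncomp <- amax
  }
  if (ncomp < 1L) stop("ncomp must be >= 1", call. = FALSE)
  x_mean <- colMeans(X); y_mean <- mean(y)
  fit <- pls1_nipals(sweep(X, 2L, x_mean), y - y_mean, ncomp)
  if (fit$ncomp < ncomp)
    warning("components truncated to ", fit$ncomp, " (rank exhausted)",
            call. = FALSE)
  B <- pls1_coef_path(fit)
  structure(list(x_mean = x_mean, y_mean = y_mean,
                 weights = fit$W, x_loadings = fit$P, y_loadings = fit$Q,
                 scores = fit$scores, coef_path = B,
                 coefficients = B[, fit$ncomp],
                 ncomp = fit$ncomp, wavelength = wl),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d components, %d bands\n",
              x$ncomp, length(x$x_mean)))
  invisible(x)
}

#' Predict from a PLS model
#'
#' Two algebraically equivalent routes are available: the compact regression
#' vector (`method = "coefficients"`, default) and the sequential score-space
#' route that projects new spectra through the weight/loading factorization
#' (`method = "scores"`). They agree to numerical precision; the score route
#' is retained as a consistency check.
#'
#' @param object A `pls_model`.
#' @param newdata Matrix or [spectra_matrix()] on the training grid.
#' @param ncomp Number of components to use (default: all fitted).
#' @param method `"coefficients"` or `"scores"`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ncomp = object$ncomp,
                              method = c("coefficients", "scores"), ...) {
  method <- match.arg(method)
  X <- unclass(as.matrix(newdata))
  if (ncol(X) != length(object$x_mean))
    stop("newdata has ", ncol(X), " bands; model was trained on ",
         length(object$x_mean), call. = FALSE)
  wl <- attr(newdata, "wavelength")
  if (!is.null(wl) && !is.null(object$wavelength) &&
      !isTRUE(all.equal(wl, object$wavelength)))
    stop("newdata wavelength grid differs from the training grid", call. = FALSE)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > object$ncomp)
    stop("ncomp out of range 1..", object$ncomp, call. = FALSE)
  Xc <- sweep(X, 2L, object$x_mean)
  if (method == "coefficients") {
    as.vector(object$y_mean + Xc %*% object$coef_path[, ncomp])
  } else {
    yhat <- rep(object$y_mean, nrow(X))
    for (a in seq_len(ncomp)) {
      t_ <- Xc %*% object$weights[, a]
      yhat <- yhat + as.vector(t_) * object$y_loadings[a]
      Xc <- Xc - tcrossprod(t_, object$x_loadings[, a])
    }
    yhat
  }
}

#' Leave-one-out cross-validation for PLS component selection
#'
#' For each candidate component count `1..max_components`, each sample is
#' left out in turn, the model is refitted on the remainder and the held-out
#' sample predicted; RMSECV is the root mean squared error of those
#' predictions. The chosen count minimises RMSECV, ties broken toward fewer
#' components (parsimony).
#'
#' @param X Spectra matrix (samples x bands).
#' @param y Numeric response.
#' @param max_components Largest component count to try (default 10); capped
#'   at `min(n - 2, p)` with a warning if larger.
#' @return A `cv_result`: list with `rmsecv` (one value per component count)
#'   and `ncomp` (the argmin).
#' @export
loo_cv <- function(X, y, max_components = 10L) {
  X <- unclass(as.matrix(X)); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3L) stop("LOO cross-validation needs at least 3 samples",
                   call. = FALSE)
  amax <- min(n - 2L, ncol(X))
  if (max_components > amax) {
    warning("max_components capped at ", amax, call. = FALSE)
    max_components <- amax
  }
  max_components <- as.integer(max_components)
  pred <- matrix(NA_real_, n, max_components)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    xm <- colMeans(Xi); ym <- mean(yi)
    fit <- pls1_nipals(sweep(Xi, 2L, xm), yi - ym, max_components)
    if (fit$ncomp == 0L) { pred[i, ] <- ym; next }
    B <- pls1_coef_path(fit)
    xc <- X[i, ] - xm
    ph <- ym + as.vector(xc %*% B)
    pred[i, seq_len(fit$ncomp)] <- ph
    if (fit$ncomp < max_components)
      pred[i, (fit$ncomp + 1L):max_components] <- ph[fit$ncomp]
  }
  rmsecv <- sqrt(colMeans((pred - y)^2))
  structure(list(rmsecv = rmsecv, ncomp = which.min(rmsecv)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> RMSECV by component count:\n")
  print(round(x$rmsecv, 4))
  cat("chosen components:", x$ncomp, "\n")
  invisible(x)
}

#' Random calibration/validation split
#'
#' Uniform random partition: `round(ratio * n)` samples go to the
#' calibration set, the rest to validation. With the study's 3/5 ratio a
#' 20-fruit group yields 12 calibration and 8 validation samples.
#'
#' @param n Number of samples (or a vector whose length is used).
#' @param ratio Calibration fraction in (0, 1), default 3/5.
#' @param seed Optional integer seed; when given the split is a deterministic
#'   function of it (the RNG state is set via [set.seed()]).
#' @return List with sorted integer index vectors `calibration` and
#'   `validation`.
#' @export
split_calibration_validation <- function(n, ratio = 3 / 5, seed = NULL) {
  if (length(n) > 1L) n <- length(n)
  n <- as.integer(n)
  if (!(ratio > 0 && ratio < 1)) stop("ratio must be in (0, 1)", call. = FALSE)
  ncal <- round(ratio * n)
  if (ncal < 1L || ncal > n - 1L)
    stop("split leaves an empty calibration or validation set", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  perm <- sample.int(n)
  list(calibration = sort(perm[seq_len(ncal)]),
       validation = sort(perm[(ncal + 1L):n]))
}

#' Prediction-set regression metrics
#'
#' `R2 = 1 - SS_res / SS_tot` with `SS_tot` about the mean of `y_true`
#' (evaluated on the set itself, so validation R2 can be negative), and
#' `RMSE = sqrt(mean((y_true - y_pred)^2))` in the response's units.
#'
#' @param y_true,y_pred Numeric vectors of equal length >= 2.
#' @return List with `r2`, `rmse`, `n`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred) || length(y_true) < 2L)
    stop("y_true and y_pred must have equal length >= 2", call. = FALSE)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0)
    stop("R2 undefined: y_true has zero variance", call. = FALSE)
  ss_res <- sum((y_true - y_pred)^2)
  list(r2 = 1 - ss_res / ss_tot,
       rmse = sqrt(mean((y_true - y_pred)^2)),
       n = length(y_true))
}
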