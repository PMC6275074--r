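#' Fisher discriminant analysis
#'
#' Canonical discriminant axes from the generalized eigenproblem of
#' between-class versus pooled within-class scatter. Axes are normalized to
#' unit within-class variance (`a' Sw a = 1`, the "unstandardized" canonical
#' coefficient convention), so Euclidean distance in canonical space is the
#' Mahalanobis distance under the pooled covariance. If the pooled
#' within-class covariance is singular (e.g. duplicated wavelengths) a ridge
#' `lambda = 1e-6 * trace(Sw)/p` is added with a warning.
#'
#' @param X Numeric matrix of features (samples x variables), typically
#'   preprocessed spectra restricted to CARS-selected wavelengths.
#' @param labels Class labels; coerced to a factor whose level order defines
#'   the class order (used for tie-breaking).
#' @return A `da_model`: class levels, class means, pooled covariance,
#'   canonical `axes` (variables x r), their `eigenvalues`, and equal priors.
#' @export
fit_lda <- function(X, labels) {
  X <- unclass(as.matrix(X)); storage.mode(X) <- "double"
  labels <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  classes <- levels(labels)
  k <- length(classes)
  if (k < 2L) stop("need at least 2 classes", call. = FALSE)
  nc <- table(labels)
  if (any(nc < 2L))
    stop("every class needs at least 2 samples; too small: ",
         paste(names(nc)[nc < 2L], collapse = ", "), call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  means <- t(vapply(classes, function(cl)
    colMeans(X[labels == cl, , drop = FALSE]), numeric(p)))
  Sw <- matrix(0, p, p)
  for (cl in classes) {
    Xc <- sweep(X[labels == cl, , drop = FALSE], 2L, means[cl, ])
    Sw <- Sw + crossprod(Xc)
  }
  Sw <- Sw / (n - k)
  gm <- colMeans(X)
  Sb <- matrix(0, p, p)
  for (j in seq_len(k)) {
    d <- means[j, ] - gm
    Sb <- Sb + nc[[j]] * tcrossprod(d)
  }
  Sb <- Sb / (k - 1)

  ridge_used <- 0
  es <- eigen(Sw, symmetric = TRUE)
  if (min(es$values) < 1e-10 * max(es$values)) {
    ridge_used <- 1e-6 * sum(diag(Sw)) / p
    warning("singular pooled covariance; ridge ", signif(ridge_used, 3),
            " added", call. = FALSE)
    es <- eigen(Sw + diag(ridge_used, p), symmetric = TRUE)
  }
  ihalf <- es$vectors %*% (t(es$vectors) / sqrt(es$values))
  sym <- ihalf %*% Sb %*% ihalf
  ee <- eigen((sym + t(sym)) / 2, symmetric = TRUE)
  r <- min(k - 1L, p)
  axes <- ihalf %*% ee$vectors[, seq_len(r), drop = FALSE]
  structure(list(classes = classes, means = means, pooled_cov = Sw,
                 axes = axes, eigenvalues = ee$values[seq_len(r)],
                 priors = rep(1 / k, k), ridge = ridge_used),
            class = "da_model")
}

#' @export
print.da_model <- function(x, ...) {
  cat(sprintf("<da_model> %d classes (%s), %d canonical axes on %d variables\n",
              length(x$classes), paste(x$classes, collapse = "/"),
              ncol(x$axes), nrow(x$axes)))
  invisible(x)
}

#' Classify samples with a fitted discriminant model
#'
#' Samples and class means are projected onto the canonical axes and each
#' sample is assigned the class with the nearest centroid (equal priors).
#' Exact ties go to the earliest class in the declared class order.
#'
#' @param model A `da_model` from [fit_lda()].
#' @param X Feature matrix on the training variable space.
#' @return Factor of predicted classes with the model's levels.
#' @export
classify <- function(model, X) {
  stopifnot(inherits(model, "da_model"))
  X <- unclass(as.matrix(X))
  if (ncol(X) != nrow(model$axes))
    stop("feature dimension does not match the trained model", call. = FALSE)
  Z <- X %*% model$axes
  M <- model$means %*% model$axes
  d2 <- outer(rowSums(Z^2), rowSums(M^2), `+`) - 2 * Z %*% t(M)
  idx <- apply(d2, 1L, which.min)  # first minimum = earliest class on ties
  factor(model$classes[idx], levels = model$classes)
}

#' Confusion matrix with row percentages
#'
#' Rows are actual classes, columns classified classes; percentages are
#' row-normalized so each row sums to 100.
#'
#' @param true,predicted Label vectors of equal length; every label must be
#'   one of `classes`.
#' @param classes Class order (default: union of factor levels).
#' @param split Tag carried in reports, e.g. `"training"` or `"testing"`.
#' @return A `confusion_matrix`: integer `counts`, numeric `percent`, `split`.
#' @export
confusion <- function(true, predicted, classes = NULL, split = "testing") {
  true <- as.character(true); predicted <- as.character(predicted)
  if (length(true) != length(predicted))
    stop("label vectors must have equal length", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(c(true, predicted)))
  bad <- setdiff(c(true, predicted), classes)
  if (length(bad) > 0L)
    stop("unseen label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  counts <- table(factor(true, classes), factor(predicted, classes))
  counts <- matrix(as.integer(counts), length(classes),
                   dimnames = list(actual = classes, classified = classes))
  rs <- rowSums(counts)
  percent <- counts / ifelse(rs == 0, 1, rs) * 100
  structure(list(counts = counts, percent = percent, split = split),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> (%s set), row %%:\n", x$split))
  print(round(cbind(x$percent, Total = rowSums(x$percent)), 1))
  invisible(x)
}

#' Write a confusion matrix as CSV
#'
#' Row-percentage layout: actual classes in rows, classified classes in
#' columns, plus a `Total` column.
#'
#' @param x A `confusion_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_confusion <- function(x, path) {
  stopifnot(inherits(x, "confusion_matrix"))
  df <- data.frame(actual = rownames(x$percent),
                   round(x$percent, 1),
                   Total = round(rowSums(x$percent), 1),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Stratified train/test split
#'
#' Per class, `round(ratio * n_class)` samples are assigned to the training
#' set and the rest to testing; the split is disjoint, exhaustive and
#' deterministic for a given seed. A class with fewer than 2 samples goes
#' entirely to training with a warning.
#'
#' @param labels Class label vector (defines `n` and the strata).
#' @param ratio Training fraction, default 3/4.
#' @param seed Optional integer seed.
#' @return List with sorted index vectors `train` and `test`.
#' @export
split_train_test <- function(labels, ratio = 3 / 4, seed = NULL) {
  labels <- factor(labels)
  if (!(ratio > 0 && ratio < 1)) stop("ratio must be in (0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  train <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < 2L) {
      warning("class '", cl, "' has < 2 samples; assigned to training",
              call. = FALSE)
      train <- c(train, idx)
      next
    }
    ntr <- min(max(1L, round(ratio * length(idx))), length(idx) - 1L)
    train <- c(train, sample(idx, ntr))
  }
  list(train = sort(train),
       test = sort(setdiff(seq_along(labels), train)))
}
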