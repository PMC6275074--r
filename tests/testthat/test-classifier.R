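test_that("two spherical classes give an axis along the mean difference", {
  set.seed(1)
  n <- 200L
  X <- rbind(matrix(rnorm(2 * n), n, 2),
             sweep(matrix(rnorm(2 * n), n, 2), 2, c(6, 3), `+`))
  labels <- rep(c("a", "b"), each = n)
  m <- fit_lda(X, labels)
  axis <- m$axes[, 1] / sqrt(sum(m$axes[, 1]^2))
  dir <- c(6, 3) / sqrt(45)
  expect_gt(abs(sum(axis * dir)), 0.98)
})

test_that("collinear class means concentrate between-class variance on one axis", {
  set.seed(2)
  centers <- rbind(c(0, 0), c(2, 1), c(4, 2))  # collinear
  X <- do.call(rbind, lapply(1:3, function(j)
    sweep(matrix(rnorm(120, 0, 0.3), 60, 2), 2, centers[j, ], `+`)))
  labels <- rep(c("a", "b", "c"), each = 60)
  m <- fit_lda(X, labels)
  ev <- pmax(m$eigenvalues, 0)
  expect_gte(ev[1] / sum(ev), 0.99)
})

test_that("duplicated feature columns trigger the ridge without changing labels", {
  set.seed(3)
  X <- rbind(matrix(rnorm(60), 30, 2),
             sweep(matrix(rnorm(60), 30, 2), 2, c(4, 4), `+`))
  labels <- rep(c("a", "b"), each = 30)
  base <- classify(fit_lda(X, labels), X)
  Xd <- cbind(X, X[, 1])  # exact duplicate -> singular pooled covariance
  expect_warning(md <- fit_lda(Xd, labels), "ridge")
  expect_gt(md$ridge, 0)
  expect_identical(classify(md, Xd), base)
})

test_that("classification agrees with MASS::lda on well-conditioned data", {
  set.seed(4)
  centers <- rbind(c(0, 0, 0), c(3, 1, -1), c(-1, 4, 2))
  X <- do.call(rbind, lapply(1:3, function(j)
    sweep(matrix(rnorm(150), 50, 3), 2, centers[j, ], `+`)))
  labels <- factor(rep(c("a", "b", "c"), each = 50))
  m <- fit_lda(X, labels)
  Xnew <- matrix(rnorm(90), 30, 3)
  ref <- MASS::lda(X, grouping = labels, prior = rep(1 / 3, 3))
  expect_identical(as.character(classify(m, Xnew)),
                   as.character(predict(ref, Xnew)$class))
})

test_that("classify returns the own class for centroids and breaks ties in order", {
  set.seed(5)
  X <- rbind(matrix(rnorm(40, 0, 0.5), 20, 2),
             sweep(matrix(rnorm(40, 0, 0.5), 20, 2), 2, c(5, 0), `+`))
  labels <- factor(rep(c("first", "second"), each = 20),
                   levels = c("first", "second"))
  m <- fit_lda(X, labels)
  expect_identical(as.character(classify(m, m$means)), c("first", "second"))
  # exact midpoint of the two projected centroids is equidistant -> first
  mid <- matrix((m$means[1, ] + m$means[2, ]) / 2, 1)
  expect_identical(as.character(classify(m, mid)), "first")
})

test_that("well-separated Gaussian classes are recovered almost perfectly", {
  set.seed(6)
  centers <- rbind(c(0, 0), c(5, 0), c(0, 5))  # 5-sd separation
  lab <- sample(1:3, 500, replace = TRUE)
  X <- t(vapply(lab, function(j) centers[j, ] + rnorm(2), numeric(2)))
  tr <- sample(500, 300)
  m <- fit_lda(X[tr, ], letters[lab[tr]])
  pred <- classify(m, X[-tr, ])
  expect_gte(mean(as.character(pred) == letters[lab[-tr]]), 0.95)
})

test_that("classification is invariant to joint invertible affine maps", {
  set.seed(7)
  X <- rbind(matrix(rnorm(90), 30, 3),
             sweep(matrix(rnorm(90), 30, 3), 2, c(3, -2, 1), `+`),
             sweep(matrix(rnorm(90), 30, 3), 2, c(-2, 3, -1), `+`))
  labels <- rep(c("a", "b", "c"), each = 30)
  Xt <- matrix(rnorm(45), 15, 3)
  base <- classify(fit_lda(X, labels), Xt)
  for (rep_ in 1:5) {
    A <- matrix(rnorm(9), 3, 3)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(9), 3, 3)
    shift <- rnorm(3)
    f <- function(M) sweep(M %*% A, 2, shift, `+`)
    expect_identical(classify(fit_lda(f(X), labels), f(Xt)), base,
                     label = paste("affine map", rep_))
  }
})

test_that("confusion matrices count, normalize and validate labels", {
  cm <- confusion(c("a", "a", "b"), c("a", "a", "b"), classes = c("a", "b"))
  expect_equal(unname(diag(cm$percent)), c(100, 100))
  one <- confusion(c("a", "a", "b", "b"), rep("a", 4), classes = c("a", "b"))
  expect_equal(unname(one$percent[, "a"]), c(100, 100))
  # hand-built 9-entry tally
  true <- c("s", "s", "s", "m", "m", "m", "g", "g", "g")
  pred <- c("s", "m", "s", "m", "m", "g", "g", "g", "g")
  cm9 <- confusion(true, pred, classes = c("s", "m", "g"))
  expect_identical(unname(cm9$counts),
                   matrix(as.integer(c(2, 0, 0, 1, 2, 0, 0, 1, 3)), 3))
  expect_equal(unname(rowSums(cm9$percent)), rep(100, 3))
  expect_error(confusion("a", "z", classes = "a"), "unseen")
})

test_that("stratified splitting keeps ratios per class and partitions", {
  labels <- rep(c("x", "y", "z"), each = 20)
  sp <- split_train_test(labels, ratio = 3 / 4, seed = 17L)
  expect_length(sp$train, 45L)
  expect_length(sp$test, 15L)
  for (cl in c("x", "y", "z"))
    expect_identical(sum(labels[sp$train] == cl), 15L)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(labels))
  expect_identical(split_train_test(labels, 3 / 4, seed = 17L), sp)
  expect_warning(split_train_test(c("x", rep("y", 9)), 0.75), "training")
})
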