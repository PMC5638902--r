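test_that("HOG descriptors are deterministic with a zero-gradient guard", {
  v <- rand_volume(c(24, 24, 10), seed = 2)
  h1 <- hog_features(v)
  h2 <- hog_features(v)
  expect_identical(h1, h2)
  expect_gt(length(h1), 0)
  # uniform volume: no gradients anywhere, all-zero descriptor
  u <- vol_image(array(5, c(24, 24, 10)))
  expect_true(all(hog_features(u) == 0))
  expect_error(hog_features(v, slices = 99), "out of range")
})

test_that("a 90-degree rotation permutes the orientation histogram", {
  bar <- matrix(0, 16, 16); bar[, 8] <- 1       # horizontal gradient pattern
  rot <- t(bar)[, 16:1]                         # rotated 90 degrees
  hb <- hog_features(vol_image(array(bar, c(16, 16, 1))), slices = 1,
                     cell = 16, orientations = 4, block = 1)
  hr <- hog_features(vol_image(array(rot, c(16, 16, 1))), slices = 1,
                     cell = 16, orientations = 4, block = 1)
  # bins shift by orientations/2 under a quarter turn
  expect_equal(hr, hb[c(3, 4, 1, 2)])
})

test_that("the MSD statistic is the subspace energy fraction", {
  set.seed(3)
  W <- matrix(0, 6, 6)
  W[upper.tri(W)] <- runif(15) * rbinom(15, 1, 0.6)
  W <- W + t(W)
  sub <- graph_subspace(W, 3)
  expect_lt(max(abs(crossprod(sub$basis) - diag(3))), 1e-10)
  expect_true(all(diff(sub$eigenvalues) >= -1e-12))
  # matches an explicit projector from a dense eigendecomposition
  x <- rnorm(6)
  L <- diag(rowSums(W)) - W
  e <- eigen(L, symmetric = TRUE)
  U <- e$vectors[, order(e$values)[1:3]]
  P <- U %*% t(U)
  expect_lt(abs(msd_statistic(x, sub) - sum((P %*% x)^2) / sum(x^2)), 1e-12)
  # in-span signals score 1, orthogonal signals score 0
  expect_equal(msd_statistic(sub$basis %*% c(1, -2, 0.5), sub), 1)
  orth <- x - P %*% x
  expect_lt(msd_statistic(orth, sub), 1e-12)
  # projection is idempotent: projecting the projected signal changes nothing
  px <- sub$basis %*% crossprod(sub$basis, x)
  expect_lt(abs(msd_statistic(px, sub) - 1), 1e-12)
  expect_error(msd_statistic(rep(0, 6), sub), "zero signal")
  expect_error(graph_subspace(W, 9), "k must be")
})

test_that("ROC curves match pair counting and bound conventions", {
  r <- roc_curve(c(0.1, 0.4, 0.35, 0.8), factor(c("a", "a", "b", "b")))
  # concordant-pair fraction over the 4 pairs = 3/4
  expect_equal(r$auc, 0.75)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(utils::tail(r$points$tpr, 1), 1)
  expect_true(all(diff(r$points$tpr) >= 0) && all(diff(r$points$fpr) >= 0))
  expect_equal(roc_curve(1:10, factor(rep(c("a", "b"), each = 5)))$auc, 1)
  set.seed(4)
  rr <- roc_curve(rnorm(4000), factor(sample(c("a", "b"), 4000, TRUE)))
  expect_lt(abs(rr$auc - 0.5), 0.05)
  expect_error(roc_curve(1:4, factor(rep("a", 4))), "both classes")
})

test_that("the ROC area agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  sc <- rnorm(300)
  lb <- factor(ifelse(sc + rnorm(300) > 0, "b", "a"), levels = c("a", "b"))
  ours <- roc_curve(sc, lb)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(lb, sc, levels = c("a", "b"),
                                           direction = "<", quiet = TRUE)))
  expect_lt(abs(ours - theirs), 1e-10)
})

test_that("paired repeated CV keeps the two arms aligned and is seeded", {
  set.seed(6)
  n <- 40; m <- 20
  mu <- c(rep(3, m / 2), rep(0, m / 2))
  X <- rbind(matrix(rnorm(n * m), n),
             sweep(matrix(rnorm(n * m), n), 2, mu, `+`))
  y <- factor(rep(c("a", "b"), each = n))
  pre <- feature_set(X, y, "uncorrected", "region_means")
  post <- feature_set(X + rnorm(length(X), 0, 0.05), y, "corrected",
                      "region_means")
  r1 <- repeated_kfold(pre, post, "lda", folds = 10, repetitions = 2,
                       seed = 9)
  r2 <- repeated_kfold(pre, post, "lda", folds = 10, repetitions = 2,
                       seed = 9)
  expect_identical(r1$errors, r2$errors)
  expect_true(all(r1$errors$error_pre >= 0 & r1$errors$error_pre <= 1))
  # label mismatch is rejected
  bad <- feature_set(X, rev(y), "corrected", "region_means")
  expect_error(repeated_kfold(pre, bad, "lda"), "share labels")
})

test_that("stratified folds test every subject exactly once per repetition", {
  set.seed(7)
  y <- factor(rep(c("a", "b"), c(23, 17)))
  fold <- pvcnet:::stratified_folds(y, 10)
  expect_length(fold, 40)
  expect_true(all(table(fold) >= 2))
  for (f in 1:10) expect_equal(nlevels(droplevels(y[fold != f])), 2L)
})

test_that("all three classifiers separate well-separated Gaussian classes", {
  set.seed(8)
  n <- 40; m <- 20
  mu <- c(rep(3, m / 2), rep(0, m / 2))   # structured mean difference
  X <- rbind(matrix(rnorm(n * m), n),
             sweep(matrix(rnorm(n * m), n), 2, mu, `+`))
  y <- factor(rep(c("a", "b"), each = n))
  pre <- feature_set(X, y, "uncorrected", "region_means")
  post <- feature_set(X + rnorm(length(X), 0, 0.05), y, "corrected",
                      "region_means")
  for (clf in c("svm", "lda", "msd")) {
    r <- suppressWarnings(repeated_kfold(pre, post, clf, folds = 10,
                                         repetitions = 3, seed = 10))
    expect_lt(mean(r$errors$error_pre), 0.05)
    expect_lt(mean(r$errors$error_post), 0.05)
    expect_gt(r$roc_pre$auc, 0.95)
  }
})
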