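test_that("classifier outputs are probabilities over 17 classes", {
  set.seed(41)
  m <- build_classifier(classifier_config(channels = c(4L, 4L, 8L)))
  fov <- toy_fov()
  # toy FOV has few pixels; embed into the 64x64 frame via the default mask
  fov64 <- fov64()
  Y <- matrix(runif(3 * fov64$n_fov), 3)
  p <- predict_classifier(m, Y, fov64)
  expect_identical(dim(p), c(3L, 17L))
  expect_equal(rowSums(p), rep(1, 3))
  expect_true(all(p >= 0))
  expect_identical(p, predict_classifier(m, Y, fov64))  # eval determinism
})

test_that("classifier overfits a trivially separable set", {
  set.seed(42)
  fov <- fov64()
  n <- 68
  labels <- rep(1:17, length.out = n)
  # class k = Gaussian bump at a class-specific position on a ring: a
  # geometrically separable pattern suited to a convolutional classifier
  ctr <- cbind(32 + 18 * cos(2 * pi * (1:17) / 17),
               32 + 18 * sin(2 * pi * (1:17) / 17))
  d2 <- function(k) (fov$pix[, 1] - ctr[k, 1])^2 + (fov$pix[, 2] - ctr[k, 2])^2
  Y <- t(vapply(labels, function(k) exp(-d2(k) / 72), numeric(fov$n_fov))) +
    matrix(rnorm(n * fov$n_fov, sd = 0.02), n)
  m <- train_classifier(Y, labels, fov,
                        classifier_config(channels = c(4L, 8L, 8L), lr = 3e-3,
                                          epochs = 40L, batch = 34L, seed = 2))
  p <- predict_classifier(m, Y, fov)
  expect_gt(mean(max.col(p) == labels), 0.9)
})

test_that("one-vs-rest AUC matches the pairwise estimator", {
  set.seed(43)
  n <- 60
  labels <- sample(1:4, n, replace = TRUE)
  probs <- matrix(runif(n * 4), n)
  probs <- probs / rowSums(probs)
  roc <- ovr_roc_auc(probs, labels)
  for (k in 1:4) {
    expect_equal(roc$per_class[[k]]$auc,
                 pairwise_auc(probs[, k], labels == k), tolerance = 1e-6)
  }
  expect_equal(roc$macro_auc,
               mean(vapply(roc$per_class, function(x) x$auc, 0)))
})

test_that("perfect, null and reversed scores give the canonical AUCs", {
  set.seed(44)
  labels <- sample(1:17, 2000, replace = TRUE)
  perfect <- matrix(0, 2000, 17); perfect[cbind(seq_len(2000), labels)] <- 1
  expect_equal(ovr_roc_auc(perfect, labels)$macro_auc, 1)
  null_probs <- matrix(runif(2000 * 17), 2000)
  null_probs <- null_probs / rowSums(null_probs)
  null_auc <- ovr_roc_auc(null_probs, labels)$macro_auc
  expect_gt(null_auc, 0.45); expect_lt(null_auc, 0.55)
  # reversing scores reflects each class AUC about 1/2
  r1 <- ovr_roc_auc(null_probs, labels)
  r2 <- ovr_roc_auc(1 - null_probs, labels)
  for (k in c(2, 9, 17))
    expect_equal(r2$per_class[[k]]$auc, 1 - r1$per_class[[k]]$auc,
                 tolerance = 1e-9)
})

test_that("macro AUC is invariant to class relabelling", {
  set.seed(45)
  n <- 300
  labels <- sample(1:5, n, replace = TRUE)
  probs <- matrix(runif(n * 5), n); probs <- probs / rowSums(probs)
  perm <- sample(5)
  a1 <- ovr_roc_auc(probs, labels)$macro_auc
  a2 <- ovr_roc_auc(probs[, perm], match(labels, perm))$macro_auc
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("absent classes are skipped with a warning", {
  set.seed(46)
  labels <- sample(1:4, 50, replace = TRUE)
  probs <- matrix(runif(50 * 5), 50); probs <- probs / rowSums(probs)
  expect_warning(r <- ovr_roc_auc(probs, labels), "not represented")
  expect_null(r$per_class[[5]])
  expect_false(is.null(r$per_class[[2]]))
})

test_that("ROC curves are monotone and the macro curve is their mean", {
  set.seed(47)
  labels <- sample(1:3, 200, replace = TRUE)
  probs <- matrix(runif(200 * 3), 200); probs <- probs / rowSums(probs)
  r <- ovr_roc_auc(probs, labels)
  for (k in 1:3) {
    expect_true(all(diff(r$per_class[[k]]$fpr) >= 0))
    expect_true(all(diff(r$per_class[[k]]$tpr) >= 0))
  }
  expect_true(all(diff(r$macro_tpr) >= -1e-12))
  expect_identical(length(r$macro_fpr), 1001L)
})
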