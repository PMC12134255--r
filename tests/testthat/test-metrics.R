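# Metric formulas against hand-computed and published worked examples.

test_that("dice and jaccard match hand counts and identities", {
  m <- matrix(0, 4, 4)
  pred <- m; pred[1, 1:2] <- 1                 # 2 px
  targ <- m; targ[1, 1:4] <- 1                 # 4 px, overlap 2
  expect_equal(dice(pred, targ), 4 / 6, tolerance = 1e-12)
  expect_equal(jaccard(pred, targ), 2 / 4, tolerance = 1e-12)
  expect_identical(dice(targ, targ), 1)        # exact, smooth cancels
  expect_identical(jaccard(targ, targ), 1)
  disj <- m; disj[4, 1:3] <- 1
  expect_lt(dice(disj, targ), 1e-20)
  expect_error(dice(pred, matrix(0, 3, 3)), "shapes differ")
  # J = D / (2 - D) on random masks
  set.seed(11)
  for (i in 1:25) {
    a <- matrix(rbinom(36, 1, 0.4), 6, 6)
    b <- matrix(rbinom(36, 1, 0.4), 6, 6)
    D <- dice(a, b); J <- jaccard(a, b)
    expect_equal(J, D / (2 - D), tolerance = 1e-12)
  }
})

test_that("hausdorff distance is directed as printed, symmetric on demand", {
  A <- matrix(c(0, 0), 1)
  B <- matrix(c(3, 4), 1)
  expect_equal(hausdorff(A, B), 5)
  A2 <- rbind(c(0, 0), c(10, 0))
  B2 <- matrix(c(0, 0), 1)
  expect_equal(hausdorff(A2, B2), 10)
  expect_equal(hausdorff(B2, A2), 0)           # asymmetry witness
  expect_equal(hausdorff(B2, A2, symmetric = TRUE), 10)
  expect_equal(hausdorff(A2, A2), 0)
  expect_error(hausdorff(A2[0, , drop = FALSE], B2), "non-empty")
})

test_that("confusion counts, rates and undefined flags", {
  cm <- confusion(c("P", "N", "N", "N"), c("P", "P", "N", "N"), positive = "P")
  expect_equal(cm$tp, 1); expect_equal(cm$fn, 1)
  expect_equal(cm$tn, 2); expect_equal(cm$fp, 0)
  expect_equal(cm$accuracy, 0.75)
  # swapping the positive class transposes the matrix
  cm2 <- confusion(c("P", "N", "N", "N"), c("P", "P", "N", "N"), positive = "N")
  expect_equal(cm2$tp, cm$tn); expect_equal(cm2$fn, cm$fp)
  # all predicted negative -> precision undefined, not zero
  cm3 <- confusion(rep("N", 3), c("P", "N", "N"), positive = "P")
  expect_true(is_undefined(cm3$precision))
  expect_error(confusion(c("P"), c("P", "N"), "P"), "lengths differ")
})

test_that("f1 and youden reproduce the published worked examples", {
  expect_equal(round(f1(0.923, 0.915), 3), 0.919)
  expect_equal(round(f1(0.961, 0.964), 3), 0.962)
  expect_equal(f1(0.5, 0.5), 0.5)
  expect_true(is_undefined(f1(0, 0)))
  expect_equal(youden(0.964, 0.915), 0.879)
  expect_equal(youden(1, 1), 1)
  expect_equal(youden(0.7, 0.3), 0, tolerance = 1e-12)  # sens = 1 - spec
})

test_that("kappa matches the published confusion matrix and closed forms", {
  cm <- confusion_from_counts(227, 19, 21, 512, positive = "benign")
  expect_equal(round(kappa_score(cm), 4), 0.8814)
  expect_equal(round(cm$accuracy, 4), 0.9487)
  perfect <- confusion_from_counts(10, 0, 0, 20)
  expect_equal(kappa_score(perfect), 1)
  onesided <- confusion_from_counts(0, 0, 5, 15)   # all predicted negative
  expect_equal(kappa_score(onesided), 0)
})

test_that("confusion_from_rates rebuilds the published test-set matrix", {
  cm <- confusion_from_rates(248, 531, 0.915, 0.964, positive = "benign")
  expect_equal(c(cm$tp, cm$fn, cm$tn, cm$fp), c(227, 21, 512, 19))
  expect_equal(round(cm$precision, 3), 0.923)     # 227/246, as printed
  ideal <- confusion_from_rates(10, 10, 1, 1)
  expect_equal(ideal$fp + ideal$fn, 0)
})

test_that("roc_auc handles separation, ties and the 4-point example", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c("N", "N", "P", "P"), "P")$auc, 1)
  expect_equal(roc_auc(rep(0.3, 6), c("N", "N", "N", "P", "P", "P"), "P")$auc, 0.5)
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c("N", "N", "P", "P"), "P")
  expect_equal(r$auc, 0.75)
  expect_equal(r$roc$fpr[1], 0); expect_equal(r$roc$tpr[1], 0)
  expect_equal(r$roc$fpr[nrow(r$roc)], 1)
  expect_error(roc_auc(1:3, rep("P", 3), "P"), "both classes")
  # invariance under strictly increasing transforms
  set.seed(4)
  s <- rnorm(30); y <- sample(c("P", "N"), 30, replace = TRUE)
  if (length(unique(y)) == 2) {
    expect_equal(roc_auc(exp(s), y, "P")$auc, roc_auc(s, y, "P")$auc)
  }
})

test_that("metric reports round-trip through JSON bit-exactly", {
  set.seed(8)
  pred <- sample(c("benign", "malignant"), 40, replace = TRUE)
  truth <- sample(c("benign", "malignant"), 40, replace = TRUE)
  scores <- runif(40)
  rep <- classification_report(pred, truth, scores, positive = "malignant")
  path <- tempfile(fileext = ".json")
  write_report(rep, path)
  back <- read_report(path)
  expect_identical(back$accuracy, rep$accuracy)
  expect_identical(back$kappa, rep$kappa)
  expect_identical(back$auc, rep$auc)
  expect_identical(back$per_class$malignant$f1, rep$per_class$malignant$f1)
  expect_identical(back$roc$tpr, rep$roc$tpr)
})

test_that("segmentation_report combines the three mask metrics", {
  m <- matrix(0, 8, 8); m[3:5, 3:5] <- 1
  r <- segmentation_report(m, m)
  expect_identical(r$dice, 1)
  expect_equal(r$hausdorff, 0)
  r2 <- segmentation_report(matrix(0, 8, 8), m)
  expect_true(is.na(r2$hausdorff))
  expect_lt(r2$dice, 1e-20)
})
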