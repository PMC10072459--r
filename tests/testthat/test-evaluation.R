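test_that("confusion matrix counts true-by-predicted cells", {
  cls <- c("N", "S", "V", "F")
  truth <- rep(cls, each = 2)
  cm <- confusion_matrix(truth, truth, cls)
  expect_equal(diag(cm), setNames(rep(2L, 4), cls))
  expect_equal(sum(cm), 8)
  all0 <- confusion_matrix(truth, rep("N", 8), cls)
  expect_equal(sum(all0[, "N"]), 8)
  expect_equal(sum(all0[, c("S", "V", "F")]), 0)
  withr::with_seed(1, {
    t2 <- sample(cls, 57, replace = TRUE)
    p2 <- sample(cls, 57, replace = TRUE)
    expect_equal(sum(confusion_matrix(t2, p2, cls)), 57)
  })
  expect_error(confusion_matrix(c("N", "Z"), c("N", "N"), cls),
               "unknown label.*Z")
})

test_that("metrics match hand-evaluated one-vs-rest definitions", {
  rep0 <- metrics_from_confusion(diag(4) * 5)
  expect_equal(rep0$macro$accuracy, 1)
  expect_equal(rep0$macro$f1, 1)
  expect_equal(rep0$score, 1)
  cm <- matrix(c(8, 2, 1, 9), 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  r <- metrics_from_confusion(cm)
  expect_equal(r$per_class$precision[1], 8 / 9, tolerance = 1e-9)
  expect_equal(r$per_class$sensitivity[1], 0.8, tolerance = 1e-9)
  expect_equal(r$per_class$f1[1], 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8),
               tolerance = 1e-9)
  expect_equal(r$macro$accuracy, 17 / 20)
  # score is exactly the squared macro F1
  expect_identical(r$score, r$macro$f1^2)
  expect_error(metrics_from_confusion(matrix(0, 3, 3)), "all-zero")
})

test_that("metrics agree with a brute-force TP/TN/FP/FN counter", {
  cls <- c("N", "S", "V", "F")
  withr::with_seed(7, {
    for (trial in 1:30) {
      n <- sample(20:60, 1)
      truth <- sample(cls, n, replace = TRUE)
      pred <- sample(cls, n, replace = TRUE)
      r <- metrics_from_confusion(confusion_matrix(truth, pred, cls))
      for (ci in seq_along(cls)) {
        tp <- sum(truth == cls[ci] & pred == cls[ci])
        fp <- sum(truth != cls[ci] & pred == cls[ci])
        fn <- sum(truth == cls[ci] & pred != cls[ci])
        tn <- n - tp - fp - fn
        expect_identical(unname(r$confusion[ci, ci]), as.integer(tp))
        prec <- if (tp + fp > 0) tp / (tp + fp) else 0
        sens <- if (tp + fn > 0) tp / (tp + fn) else 0
        expect_equal(r$per_class$precision[ci], prec, tolerance = 1e-12)
        expect_equal(r$per_class$sensitivity[ci], sens, tolerance = 1e-12)
        expect_equal(tp + tn + fp + fn, n)
      }
      # harmonic mean never exceeds the arithmetic mean
      expect_true(all(r$per_class$f1 <=
                        (r$per_class$precision + r$per_class$sensitivity) / 2 +
                        1e-12))
    }
  })
})

test_that("ROC/PR curves hit the textbook limits", {
  truth <- c(rep("A", 5), rep("B", 5))
  perfect <- cbind(c(rep(0.9, 5), rep(0.1, 5)),
                   c(rep(0.1, 5), rep(0.9, 5)))
  cur <- roc_pr_curves(perfect, truth, c("A", "B"))
  expect_equal(cur$A$auc, 1)
  expect_equal(cur$B$auc, 1)
  constant <- matrix(0.5, 10, 2)
  cur2 <- roc_pr_curves(constant, truth, c("A", "B"))
  expect_equal(cur2$A$auc, 0.5)   # chance diagonal
  expect_true(all(diff(cur2$A$roc$fpr) >= 0))
  one_class <- suppressMessages(
    roc_pr_curves(perfect, rep("A", 10), c("A", "B")))
  expect_null(one_class$B)
})

test_that("trapezoidal AUC matches the pairwise Mann-Whitney oracle", {
  withr::with_seed(9, {
    n <- 50
    truth <- sample(c("A", "B"), n, replace = TRUE)
    sc <- runif(n) + (truth == "A") * 0.3
    P <- cbind(sc, 1 - sc)
    auc <- roc_pr_curves(P, truth, c("A", "B"))$A$auc
    pos <- sc[truth == "A"]; neg <- sc[truth != "A"]
    pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    expect_equal(auc, mean(pairs), tolerance = 1e-9)
  })
})

test_that("the benchmark grid reports bounded, reproducible accuracies", {
  ds <- fixture_dataset(n_per_class = 20)
  cfg <- train_config(epochs = 3, seed = 0, batch_size = 32)
  rep1 <- suppressWarnings(suppressMessages(
    run_benchmark(ds, crs = c(0.2, 0.05), methods = c("cnn", "pca"),
                  config = cfg)))
  expect_equal(nrow(rep1), 4)
  expect_true(all(rep1$accuracy >= 0 & rep1$accuracy <= 1))
  rep2 <- suppressWarnings(suppressMessages(
    run_benchmark(ds, crs = c(0.2, 0.05), methods = c("cnn", "pca"),
                  config = cfg)))
  expect_identical(rep1, rep2)
})
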