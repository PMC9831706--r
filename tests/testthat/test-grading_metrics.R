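test_that("confusion matrix tallies actual x predicted pairs", {
  cm <- confusion_matrix(c(0, 1, 2), c(0, 1, 2), 3)
  expect_equal(unclass(cm), diag(1L, 3),
               ignore_attr = TRUE)

  cm2 <- confusion_matrix(c(0, 1), c(1, 0), 2)
  expect_equal(as.vector(unclass(cm2)), c(0L, 1L, 1L, 0L))

  # 100 random pairs against an independent tally
  set.seed(20)
  a <- sample(0:2, 100, replace = TRUE)
  p <- sample(0:2, 100, replace = TRUE)
  cm3 <- confusion_matrix(a, p, 3)
  tab <- table(factor(a, 0:2), factor(p, 0:2))
  expect_equal(unclass(cm3), unclass(tab), ignore_attr = TRUE)

  expect_error(confusion_matrix(c(0, 3), c(0, 0), 3), "out of range")
  expect_error(confusion_matrix(0, c(0, 1), 2), "equal length")
})

test_that("one-vs-rest counts follow the row/column decomposition", {
  cm5 <- read_confusion_csv(idrid_cm_path())
  # proliferative class of the 5-class matrix
  cc <- class_counts(cm5, 4)
  expect_equal(cc, list(TP = 10L, FP = 0L, FN = 3L, TN = 90L, total = 103L))

  # diagonal matrix: no false positives or negatives anywhere
  d <- confusion_matrix(0:3, 0:3, 4)
  for (k in 0:3) {
    cc <- class_counts(d, k)
    expect_equal(cc$FP, 0L)
    expect_equal(cc$FN, 0L)
  }

  # TP + FP + FN + TN is the total count for every class of any matrix
  set.seed(21)
  for (r in 1:5) {
    cmr <- confusion_matrix(sample(0:3, 60, TRUE), sample(0:3, 60, TRUE), 4)
    for (k in 0:3) {
      cc <- class_counts(cmr, k)
      expect_identical(cc$TP + cc$FP + cc$FN + cc$TN, cc$total)
    }
  }
  expect_error(class_counts(cm5, 7), "out of range")
})

test_that("per-class metrics reproduce hand-checked fractions", {
  # moderate-DR class of the 5-class matrix: TP=29 FP=25 FN=3 TN=46
  row <- class_metrics(list(TP = 29, FP = 25, FN = 3, TN = 46, total = 103))
  expect_equal(round_half_up(row[["precision"]]), 0.5370)
  expect_equal(round_half_up(row[["recall"]]), 0.9063)
  expect_equal(round_half_up(row[["accuracy"]]), 0.7282)
  expect_equal(round_half_up(row[["specificity_as_printed"]]), 0.0612)
  expect_equal(row[["specificity"]], 46 / 71)

  # perfect class (TN = 0 makes specificity and FOR degenerate 0/0 cells)
  perfect <- suppressWarnings(
    class_metrics(list(TP = 10, FP = 0, FN = 0, TN = 0, total = 10)))
  expect_equal(perfect[["precision"]], 1)
  expect_equal(perfect[["recall"]], 1)
  expect_equal(perfect[["accuracy"]], 1)

  # 0/0 cells degrade to 0 with a warning
  w <- capture_warnings(
    z <- class_metrics(list(TP = 0, FP = 0, FN = 5, TN = 5, total = 10)))
  expect_true(any(grepl("0/0 in precision", w)))
  expect_equal(z[["precision"]], 0)
  expect_equal(z[["f1"]], 0)
})

test_that("f1 lies between min and max of precision and recall", {
  set.seed(22)
  for (r in 1:30) {
    cc <- list(TP = sample(1:50, 1), FP = sample(0:50, 1),
               FN = sample(0:50, 1), TN = sample(1:50, 1))
    cc$total <- cc$TP + cc$FP + cc$FN + cc$TN
    row <- class_metrics(cc)
    pr <- row[["precision"]]; re <- row[["recall"]]
    expect_gte(row[["f1"]] + 1e-12, min(pr, re))
    expect_lte(row[["f1"]] - 1e-12, max(pr, re))
  }
})

test_that("macro average is the unweighted class mean", {
  rows <- rbind(c(recall = 0), c(recall = 1))
  expect_equal(macro_average(rows)[["recall"]], 0.5)

  same <- rbind(c(f1 = 0.7), c(f1 = 0.7), c(f1 = 0.7))
  expect_equal(macro_average(same)[["f1"]], 0.7)

  # macro recall of the 5-class report = mean of its per-class recalls
  rep5 <- report_from_cm(idrid_cm_path())
  expect_equal(round_half_up(rep5$macro[["macro_sensitivity"]]),
               round_half_up(mean(c(0.5882, 0.6, 0.9063, 0.5263, 0.7692))),
               tolerance = 1e-4)
  expect_error(macro_average(matrix(0, 0, 3)), "empty")
})

test_that("micro and macro accuracy agree only on balanced symmetric matrices", {
  sym <- matrix(c(8L, 2L, 2L, 8L), 2, 2)
  class(sym) <- c("confusion_matrix", class(sym))
  rep_sym <- metrics_report(sym)
  micro <- sum(diag(unclass(sym))) / sum(unclass(sym))
  expect_equal(rep_sym$macro[["macro_accuracy"]], micro)

  skew <- matrix(c(90L, 9L, 0L, 1L), 2, 2)
  class(skew) <- c("confusion_matrix", class(skew))
  rep_skew <- metrics_report(skew)
  micro_skew <- sum(diag(unclass(skew))) / sum(unclass(skew))
  expect_equal(rep_skew$macro[["macro_accuracy"]], micro_skew)  # 2-class: always equal
  # with >2 classes the identity genuinely breaks
  tri <- matrix(c(5L, 0L, 0L, 4L, 1L, 0L, 0L, 0L, 10L), 3, 3)
  class(tri) <- c("confusion_matrix", class(tri))
  rep_tri <- metrics_report(tri)
  micro_tri <- sum(diag(unclass(tri))) / sum(unclass(tri))
  expect_false(isTRUE(all.equal(rep_tri$macro[["macro_accuracy"]], micro_tri)))
})

test_that("AUC equals the Mann-Whitney probability with ties at 1/2", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(roc_auc(rep(1, 8), rep(0:1, 4)), 0.5)

  # one inversion in six samples, against brute-force pair counting
  s <- c(1, 2, 4, 3, 5, 6); y <- c(0, 0, 0, 1, 1, 1)
  expect_equal(roc_auc(s, y), pair_count_auc(s, y))
  expect_equal(roc_auc(s, y), 8 / 9)

  set.seed(23)
  for (r in 1:20) {
    n <- sample(6:20, 1)
    sc <- sample(1:8, n, replace = TRUE)  # ties likely
    y <- c(0, 1, sample(0:1, n - 2, TRUE))
    expect_equal(roc_auc(sc, y), pair_count_auc(sc, y), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "both label values")
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(24)
  s <- rnorm(30); y <- sample(0:1, 30, TRUE, prob = c(0.6, 0.4))
  base <- roc_auc(s, y)
  expect_equal(roc_auc(exp(s), y), base)
  expect_equal(roc_auc(2 * s + 7, y), base)
  expect_equal(roc_auc(rank(s), y), base)
})

test_that("hand-written AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(25)
  for (r in 1:5) {
    s <- rnorm(40); y <- c(0, 1, sample(0:1, 38, TRUE))
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(s, y), ref, tolerance = 1e-10)
  }
})

test_that("Youden threshold maximizes sensitivity + specificity - 1", {
  out <- youden_threshold(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  expect_equal(out$J, 1)
  expect_equal(out$sensitivity, 1)
  expect_equal(out$specificity, 1)
  expect_true(out$threshold > 3 && out$threshold < 11)

  tied <- youden_threshold(rep(2, 6), c(0, 1, 0, 1, 0, 1))
  expect_equal(tied$J, 0)

  # 8-point toy against exhaustive search
  s <- c(0.1, 0.4, 0.35, 0.8, 0.65, 0.9, 0.5, 0.2)
  y <- c(0, 0, 1, 1, 0, 1, 1, 0)
  expect_equal(youden_threshold(s, y)$J, brute_youden(s, y))

  set.seed(26)
  for (r in 1:10) {
    s <- round(runif(12), 2); y <- c(0, 1, sample(0:1, 10, TRUE))
    expect_equal(youden_threshold(s, y)$J, brute_youden(s, y))
  }
  expect_error(youden_threshold(1:3, c(0, 0, 0)), "both label values")
})

test_that("ovr_auc scores each class against the rest", {
  set.seed(27)
  probs <- matrix(runif(30), 10, 3)
  labels <- c(rep(0, 4), rep(1, 3), rep(2, 3))
  a <- ovr_auc(probs, labels)
  expect_equal(a[1], roc_auc(probs[, 1], as.integer(labels == 0)))
  expect_equal(a[3], roc_auc(probs[, 3], as.integer(labels == 2)))
  expect_true(is.na(ovr_auc(probs, rep(0, 10))[2]))
})

test_that("report round-trips a confusion matrix through CSV", {
  cm <- confusion_matrix(c(0, 0, 1, 1, 2), c(0, 1, 1, 1, 2), 3)
  path <- tempfile(fileext = ".csv")
  write_confusion_csv(cm, path)
  back <- read_confusion_csv(path)
  expect_equal(unclass(back), unclass(cm), ignore_attr = TRUE)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("class,0,1", "0,1,2"), bad)
  expect_error(read_confusion_csv(bad), "not square")
  bad2 <- tempfile(fileext = ".csv")
  writeLines(c("class,0,1", "0,1,-2", "1,0,1"), bad2)
  expect_error(read_confusion_csv(bad2), "negative")
})

test_that("identity confusion matrix scores 1 on every metric", {
  path <- tempfile(fileext = ".csv")
  eye <- confusion_matrix(0:5, 0:5, 6)
  write_confusion_csv(eye, path)
  rep6 <- report_from_cm(path)
  for (col in c("precision", "recall", "specificity", "f1", "accuracy")) {
    expect_equal(rep6$per_class[[col]], rep(1, 6))
  }
})
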