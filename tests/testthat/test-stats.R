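test_that("Dice handles identity, disjoint, overlap and empty masks", {
  a <- array(c(rep(TRUE, 100), rep(FALSE, 100)), c(10, 10, 2))
  expect_equal(dice(a, a), 1)
  b <- array(c(rep(FALSE, 100), rep(TRUE, 100)), c(10, 10, 2))
  expect_equal(dice(a, b), 0)
  # |a| = |b| = 100 with overlap 50
  c2 <- array(FALSE, c(10, 10, 2)); c2[c(51:100, 101:150)] <- TRUE
  expect_equal(dice(a, c2), 0.5)
  expect_equal(dice(a, c2), dice(c2, a))
  e <- array(FALSE, c(2, 2, 2))
  both_empty <- dice(e, e)
  expect_equal(as.numeric(both_empty), 1)
  expect_match(attr(both_empty, "note"), "empty")
  expect_error(dice(a, e), "differ")
})

test_that("confusion matrices keep vocabulary order and zero classes", {
  cm <- confusion(c(0, 1, 2, 2), c(0, 1, 2, 2), vocabulary = 0:3)
  expect_identical(dim(cm), c(4L, 4L))
  expect_equal(sum(diag(cm)), 4L)
  expect_equal(sum(cm[, "3"]), 0L)
  expect_equal(sum(cm["3", ]), 0L)
  # swapping inputs transposes the marginals
  cm2 <- confusion(c(0, 0, 1), c(0, 1, 1), vocabulary = 0:1)
  cm2t <- confusion(c(0, 1, 1), c(0, 0, 1), vocabulary = 0:1)
  expect_identical(rowSums(cm2), colSums(cm2t))
  expect_error(confusion(c(0, 9), c(0, 0), vocabulary = 0:1), "9")
})

test_that("binary metrics reproduce hand-computed values", {
  # TP 40, TN 30, FP 10, FN 20 with 'good' positive
  ref <- c(rep("good", 60), rep("poor", 40))
  pred <- c(rep("good", 40), rep("poor", 20), rep("good", 10),
            rep("poor", 30))
  cm <- confusion(ref, pred, vocabulary = c("poor", "good"))
  bm <- binary_metrics(cm, positive = "good")
  expect_equal(bm$accuracy, 0.7)
  expect_equal(bm$sensitivity, 40 / 60)
  expect_equal(bm$specificity, 0.75)
  expect_equal(bm$mcc, oracle_mcc(40, 30, 10, 20), tolerance = 1e-12)
  expect_equal(bm$mcc, 1000 / sqrt(6e6), tolerance = 1e-12)
  # perfect classifier
  cmp <- confusion(ref, ref, vocabulary = c("poor", "good"))
  bmp <- binary_metrics(cmp, positive = "good")
  expect_equal(unlist(bmp[c("accuracy", "f1", "sensitivity",
                            "specificity", "mcc")]),
               c(accuracy = 1, f1 = 1, sensitivity = 1, specificity = 1,
                 mcc = 1))
  # single-class (all-positive) reference: specificity undefined (no
  # negatives), sensitivity 1 when all predictions are positive
  cma <- confusion(rep("good", 50), rep("good", 50),
                   vocabulary = c("poor", "good"))
  bma <- binary_metrics(cma, positive = "good")
  expect_true(is.na(bma$specificity))
  expect_match(attr(bma$specificity, "undefined"), "zero denominator")
  expect_true("specificity" %in% bma$undefined)
  expect_equal(bma$sensitivity, 1)
  # all predictions positive with both classes present: MCC undefined
  # (an empty predicted-negative marginal), specificity well-defined at 0
  cmb <- confusion(ref, rep("good", 100), vocabulary = c("poor", "good"))
  bmb <- binary_metrics(cmb, positive = "good")
  expect_equal(bmb$specificity, 0)
  expect_true(is.na(bmb$mcc))
  expect_equal(bmb$sensitivity, 1)
})

test_that("multi-class accuracy and recall follow the definitions", {
  d <- diag(c(3L, 2L, 4L, 1L))
  dimnames(d) <- list(reference = 0:3, prediction = 0:3)
  expect_equal(multiclass_accuracy(d), 1)
  u <- matrix(1L, 4, 4, dimnames = list(reference = 0:3, prediction = 0:3))
  expect_equal(multiclass_accuracy(u), 0.25)
  expect_error(multiclass_accuracy(matrix(0L, 2, 2)), "empty")
  z <- u; z["2", ] <- 0L
  rec <- per_class_recall(z, "2")
  expect_true(is.na(rec))
  expect_match(attr(rec, "undefined"), "absent")
  expect_equal(per_class_recall(u, "1"), 0.25)
})

test_that("AUC matches pair enumeration on the worked examples", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)
  expect_equal(roc_auc(c(5, 5, 5, 5), c(0, 1, 0, 1))$auc, 0.5)
  expect_equal(roc_auc(c(10, 20, 1, 2), c(1, 1, 0, 0))$auc, 1)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC equals the brute-force oracle and pROC on random data", {
  set.seed(12)
  for (i in 1:60) {
    n <- sample(6:40, 1)
    sc <- sample(round(runif(n, 0, 20), 1))  # many ties
    lb <- as.integer(runif(n) > 0.4)
    if (length(unique(lb)) < 2) lb[1:2] <- c(0L, 1L)
    a <- roc_auc(sc, lb)
    expect_equal(a$auc, oracle_auc(sc, lb), tolerance = 1e-12)
    # complement symmetry
    expect_equal(roc_auc(-sc, lb)$auc, 1 - a$auc, tolerance = 1e-12)
  }
  pr <- suppressMessages(as.numeric(pROC::auc(
    pROC::roc(c(0, 0, 1, 1, 1, 0), c(0.2, 0.7, 0.6, 0.9, 0.4, 0.1),
              direction = "<", quiet = TRUE))))
  expect_equal(roc_auc(c(0.2, 0.7, 0.6, 0.9, 0.4, 0.1),
                       c(0, 0, 1, 1, 1, 0))$auc, pr, tolerance = 1e-12)
})

test_that("Spearman correlation matches the classical formula and cor.test", {
  s <- spearman_cor(c(1, 2, 3), c(3, 1, 2))
  expect_equal(s$rho, -0.5, tolerance = 1e-12)
  expect_equal(spearman_cor(1:10, exp(1:10))$rho, 1)
  set.seed(4)
  x <- rnorm(25); y <- x + rnorm(25, 0, 2)
  a <- spearman_cor(x, y)
  b <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(a$rho, unname(b$estimate), tolerance = 1e-12)
  expect_equal(a$rho, spearman_cor(y, x)$rho)
  const <- spearman_cor(rep(1, 5), 1:5)
  expect_true(is.na(const$rho))
  expect_match(attr(const$rho, "undefined"), "rank variance")
})

test_that("ICC(2,1) reproduces the hand ANOVA and penalizes offsets", {
  x <- cbind(1:4, 2:5)  # rater2 = rater1 + 1
  r <- icc21(x)
  expect_equal(r$msr, 10 / 3, tolerance = 1e-12)
  expect_equal(r$msc, 2, tolerance = 1e-12)
  expect_equal(r$mse, 0, tolerance = 1e-12)
  expect_equal(r$icc, 10 / 13, tolerance = 1e-12)
  # identical raters over varying targets: exactly 1
  expect_equal(icc21(cbind(c(1, 5, 9), c(1, 5, 9)))$icc, 1)
  # absolute agreement <= consistency form on offset data
  consistency <- (r$msr - r$mse) / (r$msr + (ncol(x) - 1) * r$mse)
  expect_lte(r$icc, consistency)
  # constant matrix: undefined, flagged
  cc <- icc21(matrix(3, 4, 2))
  expect_true(is.na(cc$icc))
  # random matrices match the brute-force ANOVA oracle
  set.seed(19)
  for (i in 1:40) {
    n <- sample(3:12, 1); k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k), n, k)
    expect_equal(icc21(m)$icc, oracle_icc21(m), tolerance = 1e-10)
  }
})

test_that("ICC confidence interval brackets the estimate", {
  set.seed(5)
  m <- matrix(rnorm(10 * 3), 10, 3) + rnorm(10)
  r <- icc21(m)
  expect_lte(r$ci[1], r$icc)
  expect_gte(r$ci[2], r$icc)
  expect_gte(r$ci[2], r$ci[1])
})

test_that("metrics report bundles components and prints", {
  cm <- confusion(c("poor", "good", "good", "poor"),
                  c("poor", "good", "poor", "poor"),
                  vocabulary = c("poor", "good"))
  rep <- metrics_report(dsc_mean = 0.8, cm = cm,
                        auc = roc_auc(c(1, 4, 3, 2), c(0, 1, 1, 0)),
                        spearman = spearman_cor(1:4, c(1, 3, 2, 4)),
                        icc = icc21(cbind(1:4, c(1, 2, 4, 4))), n = 4)
  expect_s3_class(rep, "metrics_report")
  expect_equal(rep$binary$accuracy, 0.75)
  out <- capture.output(print(rep))
  expect_true(any(grepl("mean DSC", out)))
  expect_true(any(grepl("ICC", out)))
})
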