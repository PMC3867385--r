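test_that("confusion counts enumerate correctly", {
  y <- c(1, 1, -1, -1)
  expect_identical(confusionCounts(y, y),
                   c(tp = 2L, fp = 0L, tn = 2L, fn = 0L))
  expect_identical(confusionCounts(y, -y),
                   c(tp = 0L, fp = 2L, tn = 0L, fn = 2L))
  expect_identical(confusionCounts(y, c(1, -1, 1, -1)),
                   c(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  expect_error(confusionCounts(y, y[1:3]), "lengths differ")
})

test_that("the five measures reproduce hand-computed values and saturate at perfection", {
  m <- classMeasures(c(tp = 5, fp = 1, tn = 8, fn = 2))
  expect_equal(m, c(TPR = 5 / 7, TNR = 8 / 9, PPV = 5 / 6,
                    NPV = 4 / 5, ACC = 13 / 16))
  expect_equal(classMeasures(c(tp = 9, fp = 0, tn = 4, fn = 0)),
               c(TPR = 1, TNR = 1, PPV = 1, NPV = 1, ACC = 1))
})

test_that("the accuracy decomposition identity holds on random count tuples", {
  withr::local_seed(19)
  for (i in 1:500) {
    ct <- stats::setNames(sample(0:30, 4, replace = TRUE),
                          c("tp", "fp", "tn", "fn"))
    if (sum(ct) == 0) next
    m <- classMeasures(ct)
    n <- sum(ct)
    lhs <- m[["ACC"]]
    rhs <- (ifelse(is.na(m[["TPR"]]), 0, m[["TPR"]]) * (ct[["tp"]] + ct[["fn"]]) +
            ifelse(is.na(m[["TNR"]]), 0, m[["TNR"]]) * (ct[["tn"]] + ct[["fp"]])) / n
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("zero denominators propagate as missing values", {
  m <- classMeasures(c(tp = 0, fp = 0, tn = 5, fn = 3))
  expect_true(is.na(m[["PPV"]]))
  expect_false(is.na(m[["ACC"]]))
})

test_that("ROC behaves at the extremes and matches an independent AUC", {
  ## perfect separation
  r <- rocCurve(c(3, 2, 1, -1, -2), c(1, 1, 1, -1, -1))
  expect_equal(r$auc, 1)
  ## reversing the scores mirrors the AUC
  withr::local_seed(4)
  sc <- rnorm(200); y <- sample(c(-1, 1), 200, replace = TRUE)
  expect_equal(rocCurve(-sc, y)$auc, 1 - rocCurve(sc, y)$auc,
               tolerance = 1e-12)
  ## label-independent scores give chance AUC
  withr::local_seed(44)
  y2 <- sample(c(-1, 1), 2000, replace = TRUE)
  expect_lt(abs(rocCurve(rnorm(2000), y2)$auc - 0.5), 0.05)
  ## cross-check against pROC on a generic instance
  a <- pROC::auc(pROC::roc(response = factor(y, levels = c(-1, 1)),
                           predictor = sc, quiet = TRUE,
                           direction = "<"))
  expect_equal(rocCurve(sc, y)$auc, as.numeric(a), tolerance = 1e-10)
  ## constant scores warn and fall back to the diagonal
  expect_warning(rc <- rocCurve(rep(1, 10), rep(c(-1, 1), 5)),
                 "constant")
  expect_equal(rc$auc, 0.5)
})

test_that("the deployed operating point lies on its own ROC curve", {
  withr::local_seed(10)
  sc <- rnorm(100); y <- sign(sc + rnorm(100))
  r <- rocCurve(sc, y)
  cm <- classMeasures(confusionCounts(y, ifelse(sc >= 0, 1, -1)))
  i <- which(abs(r$fpr - (1 - cm[["TNR"]])) < 1e-12 &
             abs(r$tpr - cm[["TPR"]]) < 1e-12)
  expect_gte(length(i), 1)
})

test_that("vertical ROC averaging reduces identical curves to themselves", {
  withr::local_seed(12)
  sc <- rnorm(80); y <- sign(sc + rnorm(80, sd = 0.7))
  r <- rocCurve(sc, y)
  av <- averageRoc(list(r, r, r))
  expect_equal(max(av@tprSd), 0)
  expect_equal(av@aucMean, r$auc)
  expect_equal(av@tprMean[length(av@tprMean)], 1) # tpr at fpr = 1
  expect_true(all(diff(av@tprMean) >= -1e-9))
})

test_that("the AUC of the averaged curve matches the average member AUC", {
  withr::local_seed(23)
  curves <- lapply(1:12, function(i) {
    sc <- rnorm(150); y <- sign(sc + rnorm(150, sd = 0.9))
    rocCurve(sc, y)
  })
  av <- averageRoc(curves)
  aucOfMean <- sum(diff(av@fprGrid) *
                   (utils::head(av@tprMean, -1) +
                    utils::tail(av@tprMean, -1)) / 2)
  expect_lt(abs(aucOfMean - av@aucMean), 0.01)
})

test_that("univariate screening is calibrated under the null and powered under signal", {
  ## null: p-values from effect-free cohorts are uniform over seeds
  pv <- unlist(lapply(1:60, function(s) {
    pp <- plantedPanelCohort(integer(), numeric(), nPos = 300,
                             nNeg = 300, seed = 900 + s)
    X <- biomarkerMatrix(pp$cohort)
    y <- ifelse(
      SummarizedExperiment::colData(pp$cohort)$trueGroup < 3, 1, -1)
    univariatePvalues(X, y)$p.value
  }))
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.001)
  ## power: a planted effect of 2 SD at n = 600 is overwhelming
  pp <- plantedPanelCohort("Bands", 2.0, nPos = 300, nNeg = 300,
                           seed = 61)
  X <- biomarkerMatrix(pp$cohort)
  y <- ifelse(SummarizedExperiment::colData(pp$cohort)$trueGroup < 3,
              1, -1)
  tab <- univariatePvalues(X, y)
  expect_lt(tab$p.value[tab$biomarker == "Bands"], 1e-6)
  ## Mann-Whitney variant is labeled
  tabW <- univariatePvalues(X, y, test = "wilcoxon")
  expect_true(all(tabW$test == "wilcoxon"))
  ## degenerate biomarker flagged with p = 1
  X2 <- cbind(X, Const = 1)
  tab2 <- univariatePvalues(X2, y)
  expect_true(tab2$degenerate[tab2$biomarker == "Const"])
  expect_equal(tab2$p.value[tab2$biomarker == "Const"], 1)
})

test_that("permuted labels keep the type-I error near its nominal level", {
  fx <- plantedFixture(seed = 3)
  hits <- unlist(lapply(1:40, function(s) {
    yp <- withr::with_seed(s, sample(fx$y))
    univariatePvalues(fx$X, yp)$p.value < 0.05
  }))
  expect_lt(abs(mean(hits) - 0.05), 0.03)
})
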