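test_that("cohort generation is bit-identical under a fixed seed", {
  spec <- defaultCohortSpec(nPos = 40, nNeg = 80, seed = 123)
  c1 <- generateCohort(spec)
  c2 <- generateCohort(spec)
  expect_identical(serialize(biomarkerMatrix(c1), NULL),
                   serialize(biomarkerMatrix(c2), NULL))
  expect_identical(
    as.data.frame(SummarizedExperiment::colData(c1)),
    as.data.frame(SummarizedExperiment::colData(c2)))
  ## and the RNG stream of the caller is not disturbed
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generateCohort(spec)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("pooled Bands marginal reproduces its anchored mean at large n", {
  spec <- defaultCohortSpec(nPos = 5000, nNeg = 5000, seed = 202)
  X <- biomarkerMatrix(generateCohort(spec))
  se <- sd(X[, "Bands"]) / sqrt(nrow(X))
  expect_lt(abs(mean(X[, "Bands"]) - 7.92), 2 * se)
})

test_that("per-group sample moments converge to the specification", {
  spec <- defaultCohortSpec(nPos = 10000, nNeg = 10000, seed = 77)
  X <- biomarkerMatrix(generateCohort(spec))
  grp <- rep(c("pos", "neg"), each = 10000)
  for (j in BIOMARKERS) {
    for (g in c("pos", "neg")) {
      m <- if (g == "pos") spec@meanPos[j] else spec@meanNeg[j]
      v <- X[grp == g, j]
      expect_lt(abs(mean(v) - m), 3 * sd(v) / sqrt(length(v)))
    }
  }
  expect_true(all(X >= 0))
})

test_that("the generated correlation structure is unbiased for the target", {
  ## the single-cohort Frobenius distance sits on the sampling-noise
  ## floor, so bias is tested on the average of three seeds
  acc <- 0
  spec <- NULL
  for (s in 1:3) {
    spec <- defaultCohortSpec(nPos = 20000, nNeg = 20000, seed = 400 + s)
    X <- biomarkerMatrix(generateCohort(spec))
    acc <- acc + cor(X[seq_len(20000), ])
  }
  D <- acc / 3 - spec@corr
  expect_lt(sqrt(sum(D[upper.tri(D)]^2)), 0.05)
})

test_that("a custom correlation target is honored (Bands-CD64 above Bands-Plt)", {
  corr <- diag(10)
  dimnames(corr) <- list(BIOMARKERS, BIOMARKERS)
  corr["Bands", "CD64"] <- corr["CD64", "Bands"] <- 0.6
  corr["Bands", "Plt"] <- corr["Plt", "Bands"] <- 0.1
  spec <- cohortSpec(
    nPos = 10000, nNeg = 10000,
    meanPos = stats::setNames(c(18, 14, 15.5, 47, 231, 40, 8, 35, 8, 3),
                              BIOMARKERS),
    meanNeg = stats::setNames(c(18, 14, 15.5, 47, 231, 40, 8, 35, 8, 3),
                              BIOMARKERS),
    sdPos = stats::setNames(c(6, 8, 2.5, 7, 103, 17, 8, 12, 4, 2.4),
                            BIOMARKERS),
    sdNeg = stats::setNames(c(6, 8, 2.5, 7, 103, 17, 8, 12, 4, 2.4),
                            BIOMARKERS),
    corr = corr, informative = integer(), seed = 9)
  X <- biomarkerMatrix(generateCohort(spec))
  expect_gt(abs(cor(X[, "Bands"], X[, "CD64"])),
            abs(cor(X[, "Bands"], X[, "Plt"])))
  expect_gt(cor(X[, "Bands"], X[, "CD64"]), 0.5)
})

test_that("with no informative set the two-sample t statistics are standard normal over seeds", {
  tstats <- unlist(lapply(1:60, function(s) {
    pp <- plantedPanelCohort(integer(), numeric(), nPos = 150,
                             nNeg = 150, seed = 7000 + s)
    X <- biomarkerMatrix(pp$cohort)
    vapply(seq_len(ncol(X)), function(j)
      stats::t.test(X[1:150, j], X[151:300, j])$statistic, numeric(1))
  }))
  expect_gt(stats::ks.test(tstats, "pnorm")$p.value, 0.001)
  ## the 10 statistics per seed are correlated, so the effective
  ## sample is nearer 60 than 600; bound accordingly
  expect_lt(abs(mean(tstats)), 0.15)
  expect_lt(abs(sd(tstats) - 1), 0.15)
})

test_that("planted effects are recoverable and null panels stay quiet", {
  ## a single planted marker dominates the univariate correlations
  fx <- plantedFixture(seed = 1)
  pp <- plantedPanelCohort("Bands", 2.0, nPos = 300, nNeg = 300, seed = 5)
  X <- biomarkerMatrix(pp$cohort)
  y <- ifelse(SummarizedExperiment::colData(pp$cohort)$trueGroup < 3,
              1, -1)
  cors <- abs(drop(cor(X, y)))
  expect_equal(BIOMARKERS[which.max(cors)], "Bands")
  ## null case: all |cor with label| < 0.15 in at least 95 of 100 seeds
  ok <- vapply(1:100, function(s) {
    pp0 <- plantedPanelCohort(integer(), numeric(), nPos = 300,
                              nNeg = 300, seed = 5000 + s)
    X0 <- biomarkerMatrix(pp0$cohort)
    y0 <- ifelse(
      SummarizedExperiment::colData(pp0$cohort)$trueGroup < 3, 1, -1)
    all(abs(drop(cor(X0, y0))) < 0.15)
  }, logical(1))
  expect_gte(sum(ok), 95)
  ## determinism of the harness
  a <- plantedPanelCohort("WBC", 1, nPos = 50, nNeg = 50, seed = 3)
  b <- plantedPanelCohort("WBC", 1, nPos = 50, nNeg = 50, seed = 3)
  expect_identical(biomarkerMatrix(a$cohort), biomarkerMatrix(b$cohort))
})

test_that("invalid specifications are rejected with diagnostics", {
  m <- stats::setNames(rep(10, 10), BIOMARKERS)
  s <- stats::setNames(rep(2, 10), BIOMARKERS)
  badCorr <- matrix(0.9, 10, 10); diag(badCorr) <- 1
  badCorr[1, 2] <- badCorr[2, 1] <- -0.9 # indefinite
  dimnames(badCorr) <- list(BIOMARKERS, BIOMARKERS)
  expect_error(cohortSpec(10, 10, m, m, s, s, badCorr, integer()),
               "positive definite")
  ## group means must not differ outside the informative set
  m2 <- m; m2["Hgb"] <- 11
  expect_error(cohortSpec(10, 10, m2, m, s, s, diag(10), integer()),
               "informative")
  ## too-small groups warn but do not error
  expect_warning(
    generateCohort(defaultCohortSpec(nPos = 5, nNeg = 30, seed = 2)),
    "unstable")
})

test_that("score inputs obey the CBC identities and labels match the planted prevalence", {
  spec <- defaultCohortSpec(nPos = 120, nNeg = 240, seed = 55)
  coh <- generateCohort(spec)
  cd <- SummarizedExperiment::colData(coh)
  X <- biomarkerMatrix(coh)
  expect_equal(cd$anc, unname(X[, "WBC"] * X[, "Segs"] * 10))
  ## ABC may be nudged for a few score-consistency records; the
  ## identity holds for all others
  raw <- X[, "WBC"] * X[, "Bands"] * 10
  adj <- S4Vectors::metadata(coh)$nAdjustedScore
  expect_lte(sum(abs(cd$abc - raw) > 1e-9), adj)
  expect_true(all(cd$itRatio >= 0 & cd$itRatio <= 1))
  ## group-2/group-3 definitions are consistent with the score rule,
  ## so relabeling reproduces the planted prevalence exactly
  lab <- makeLabels(coh)
  expect_identical(sepsisGroups(lab),
                   as.integer(cd$trueGroup))
  expect_equal(mean(sepsisLabels(lab) > 0), 120 / 360)
})
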