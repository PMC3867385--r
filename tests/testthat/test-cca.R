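test_that("canonical correlation of the label with itself is 1, with an orthogonal column 0", {
  y <- rep(c(-1, 1), each = 10)
  expect_equal(canonicalCorrelation(matrix(y), y), 1)
  x <- rep(c(-1, 1), times = 10) # orthogonal to centered y
  expect_equal(canonicalCorrelation(matrix(x), y), 0, tolerance = 1e-12)
})

test_that("canonical correlation equals sqrt(R^2) of an OLS fit and the eigenproblem solution", {
  for (s in 1:25) {
    withr::local_seed(s)
    X <- matrix(rnorm(120), 40, 3)
    y <- sample(c(-1, 1), 40, replace = TRUE)
    if (length(unique(y)) == 1) y[1] <- -y[1]
    rho <- canonicalCorrelation(X, y)
    ## oracle 1: least squares with intercept
    r2 <- summary(stats::lm(y ~ X))$r.squared
    expect_equal(rho, sqrt(r2), tolerance = 1e-10)
    ## oracle 2: generalized eigenproblem route
    ## rho^2 = sigma_xy' Sigma_xx^+ sigma_xy / sigma_yy
    Sxx <- stats::cov(X); sxy <- stats::cov(X, y)
    rho2 <- drop(t(sxy) %*% pracma::pinv(Sxx) %*% sxy) / stats::var(y)
    expect_equal(rho, sqrt(rho2), tolerance = 1e-10)
  }
})

test_that("rank-deficient subsets are handled by the pseudo-inverse without crashing", {
  withr::local_seed(3)
  x <- rnorm(30)
  X <- cbind(x, x, rnorm(30)) # duplicated column
  y <- sign(x + rnorm(30, sd = 0.5))
  rho <- canonicalCorrelation(X, y)
  expect_true(rho >= 0 && rho <= 1)
  ## equals the full-rank value from the deduplicated design
  expect_equal(rho, canonicalCorrelation(X[, c(1, 3)], y),
               tolerance = 1e-8)
})

test_that("exhaustive selection is per-k optimal, monotone, and annotates enter/leave", {
  withr::local_seed(11)
  X <- matrix(rnorm(90 * 6), 90, 6)
  colnames(X) <- paste0("bm", 1:6)
  y <- sign(X[, 2] - X[, 5] + rnorm(90))
  path <- bestSubsets(X, y)
  tb <- selectionTable(path)
  ## brute-force oracle at each k
  for (k in 1:6) {
    combos <- combn(6, k)
    rhos <- apply(combos, 2, function(S)
      canonicalCorrelation(X[, S, drop = FALSE], y))
    expect_equal(tb$rho[k], max(rhos), tolerance = 1e-9)
    expect_equal(sort(tb$subset[[k]]),
                 sort(combos[, which.max(rhos)]))
  }
  ## monotone nondecreasing in k; k = p is the full multiple correlation
  expect_true(all(diff(tb$rho) >= -1e-12))
  expect_equal(tb$rho[6], canonicalCorrelation(X, y), tolerance = 1e-12)
  ## enter/leave are exact set differences of consecutive winners
  for (k in 2:6) {
    ent <- setdiff(tb$subset[[k]], tb$subset[[k - 1]])
    lev <- setdiff(tb$subset[[k - 1]], tb$subset[[k]])
    expect_equal(tb$enter[k], paste(colnames(X)[ent], collapse = ","))
    expect_equal(tb$leave[k], paste(colnames(X)[lev], collapse = ","))
  }
})

test_that("ties break to the lexicographically first subset", {
  withr::local_seed(5)
  x <- rnorm(40)
  X <- cbind(a = x, b = x, c = rnorm(40)) # columns 1 and 2 identical
  y <- sign(x + rnorm(40, sd = 0.3))
  tb <- selectionTable(bestSubsets(X, y, kRange = 1))
  expect_equal(tb$subset[[1]], 1L)
})

test_that("forward selection picks the informative column first and decouples on orthonormal designs", {
  withr::local_seed(9)
  X <- matrix(rnorm(200 * 5), 200, 5)
  colnames(X) <- paste0("bm", 1:5)
  y <- sign(X[, 4] + rnorm(200, sd = 0.4))
  expect_equal(forwardSelection(X, y)[1], "bm4")
  ## orthonormal design: FS order equals ranking by |cor(x_j, y)|
  Q <- qr.Q(qr(matrix(rnorm(60 * 4), 60, 4)))
  colnames(Q) <- paste0("q", 1:4)
  yq <- Q %*% c(0.5, -2, 1.2, 0.1) + rnorm(60, sd = 0.1)
  fs <- forwardSelection(Q, yq)
  expect_equal(fs, colnames(Q)[order(-abs(drop(cor(Q, yq))))])
})

test_that("a suppressor design separates greedy forward selection from the exhaustive optimum", {
  ## x1 barely correlated with y alone, but y ~ x1 - x2 exactly;
  ## x3 moderately correlated with y.  FS grabs x3 first, while the
  ## exhaustive best pair is {x1, x2}.
  withr::local_seed(13)
  n <- 300
  x2 <- rnorm(n)
  x1 <- x2 + rnorm(n, sd = 0.3)
  y <- (x1 - x2) * 3 + rnorm(n, sd = 0.1)
  x3 <- y * 0.3 + rnorm(n, sd = 1)
  X <- cbind(x1 = x1, x2 = x2, x3 = x3)
  path <- bestSubsets(X, y)
  best2 <- sort(selectionTable(path)$subset[[2]])
  fs2 <- sort(match(selectionTable(path, "fs")[1:2], colnames(X)))
  expect_equal(best2, c(1L, 2L))
  expect_false(identical(best2, fs2))
})

test_that("within-group correlation matrices behave and reflect the generator's structure", {
  withr::local_seed(2)
  x <- rnorm(50)
  X <- cbind(a = x, b = x, c = rnorm(50))
  y <- rep(c(1, -1), 25)
  gw <- groupwiseCorrelations(X, y)
  expect_equal(gw$septic["a", "b"], 1)
  expect_equal(diag(gw$septic), rep(1, 3), ignore_attr = TRUE)
  expect_equal(diag(gw$nonseptic), rep(1, 3), ignore_attr = TRUE)

  ## generated cohort: Bands-CD64 beats Bands-Plt in magnitude in both
  ## group-wise sample matrices
  spec <- defaultCohortSpec(nPos = 10000, nNeg = 10000, seed = 31)
  coh <- generateCohort(spec)
  Xc <- biomarkerMatrix(coh)
  yc <- ifelse(SummarizedExperiment::colData(coh)$trueGroup < 3, 1, -1)
  gwc <- groupwiseCorrelations(Xc, yc)
  for (M in list(gwc$septic, gwc$nonseptic))
    expect_gt(abs(M["Bands", "CD64"]), abs(M["Bands", "Plt"]))
})

test_that("enumeration refuses panels beyond the guard with guidance", {
  X <- matrix(rnorm(30 * 26), 30, 26)
  expect_error(bestSubsets(X, rep(c(-1, 1), 15)), "forwardSelection")
})
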