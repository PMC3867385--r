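test_that("the 1-norm SVM solves the separable toy problem exactly", {
  ## {(x=-1, y=-1), (x=+1, y=+1)} with large costs: the minimum-L1
  ## separator with active margins is w = 1, b = 0
  f <- fitSSVM(matrix(c(-1, 1), 2, 1), c(-1, 1), cPos = 100, cNeg = 100)
  expect_equal(unname(f$model@w), 1, tolerance = 1e-10)
  expect_equal(f$model@b, 0, tolerance = 1e-10)
  expect_equal(f$objective, 1, tolerance = 1e-10)
})

test_that("a pure-noise feature appended to separable data gets weight exactly zero", {
  withr::local_seed(21)
  sep <- makeSeparable(n = 40, k = 1, seed = 21)
  X <- cbind(sep$X, noise = rnorm(40))
  f <- fitSSVM(X, sep$y, cPos = 10, cNeg = 10)
  expect_equal(unname(f$model@w["noise"]), 0, tolerance = 1e-10)
  expect_gt(abs(f$model@w[1]), 0)
})

test_that("dual and primal LP routes agree to 1e-8 and satisfy optimality against probes", {
  for (s in 1:20) {
    z <- randomInstance(n = 30, k = 5, seed = s)
    fd <- fitSSVM(z$X, z$y, z$cPos, z$cNeg, method = "dual")
    fp <- fitSSVM(z$X, z$y, z$cPos, z$cNeg, method = "primal")
    expect_equal(fd$objective, fp$objective, tolerance = 1e-8)
    ## no feasible point constructed by the suite can beat the optimum
    withr::local_seed(1000 + s)
    for (j in 1:20) {
      w <- fd$model@w + rnorm(5, sd = 0.3)
      b <- fd$model@b + rnorm(1, sd = 0.3)
      expect_gte(ssvmObjective(z$X, z$y, z$ci, w, b),
                 fd$objective - 1e-8)
    }
  }
})

test_that("slack variables are consistent with the hinge at the solution", {
  z <- randomInstance(n = 40, k = 4, seed = 77)
  fp <- fitSSVM(z$X, z$y, z$cPos, z$cNeg, method = "primal")
  f <- drop(z$X %*% fp$model@w) + fp$model@b
  hinge <- pmax(0, 1 - z$y * f)
  expect_true(all(fp$xi >= hinge - 1e-8))
  expect_true(all(fp$xi >= -1e-9))
  ## replacing xi by the hinge leaves the objective unchanged
  expect_equal(sum(abs(fp$model@w)) + sum(z$ci * hinge),
               fp$objective, tolerance = 1e-8)
})

test_that("balanced costs equalize the class totals exactly and scale as stated", {
  cc <- balancedCosts(30, 60, scale = 1)
  expect_equal(cc$cPos, 1.5)
  expect_equal(cc$cNeg, 0.75)
  expect_identical(cc$cPos * 30, cc$cNeg * 60)
  for (np in c(1, 7, 50, 333)) for (nn in c(2, 13, 100)) {
    cc <- balancedCosts(np, nn, scale = 2.5)
    expect_equal(cc$cPos * np, cc$cNeg * nn, tolerance = 1e-15)
  }
  cc <- balancedCosts(25, 25, scale = 3)
  expect_equal(cc$cPos, 3)
  expect_equal(cc$cNeg, 3)
})

test_that("rescaling the costs leaves predictions on separable data unchanged", {
  sep <- makeSeparable(n = 80, k = 3, seed = 5)
  f1 <- fitSSVM(sep$X, sep$y, scale = 1)
  f2 <- fitSSVM(sep$X, sep$y, scale = 10)
  p1 <- predict(f1$model, sep$X)$label
  p2 <- predict(f2$model, sep$X)$label
  expect_identical(p1, p2)
  expect_identical(p1, sep$y)
})

test_that("fewer weights survive as the slack costs weaken", {
  z <- randomInstance(n = 60, k = 6, seed = 12)
  nz <- vapply(c(3, 1, 0.3, 0.1, 0.03), function(s) {
    f <- fitSSVM(z$X, z$y, scale = s)
    sum(abs(f$model@w) > 1e-9)
  }, numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("the ensemble reduces to a single fit when resampling is disabled, and is seed-deterministic", {
  sep <- makeSeparable(n = 50, k = 3, seed = 8)
  ens <- bootstrapBag(sep$X, sep$y, B = 1, seed = 4, resample = FALSE)
  single <- fitSSVM(sep$X, sep$y)
  expect_equal(drop(ens@W), single$model@w, tolerance = 1e-10)
  expect_equal(ens@b, single$model@b, tolerance = 1e-10)
  ## ensemble of identical members scores like the member
  ens3 <- bootstrapBag(sep$X, sep$y, B = 3, seed = 4, resample = FALSE)
  expect_equal(decisionValues(ens3, sep$X),
               decisionValues(single$model, sep$X), tolerance = 1e-10)
  ## determinism
  e1 <- bootstrapBag(sep$X, sep$y, B = 10, seed = 99)
  e2 <- bootstrapBag(sep$X, sep$y, B = 10, seed = 99)
  expect_identical(e1@W, e2@W)
  expect_identical(e1@b, e2@b)
})

test_that("prediction is inclusive at zero and linear in the members", {
  m <- new("LinearDecisionFunction", w = c(a = 1), b = -2,
           mu = c(a = 0), sigma = c(a = 1))
  p <- predict(m, matrix(2, 1, 1, dimnames = list(NULL, "a")))
  expect_equal(p$score, 0)
  expect_equal(p$label, 1) # score exactly 0 is a positive diagnosis
  ## negating weights and biases negates every score
  sep <- makeSeparable(n = 30, k = 2, seed = 3)
  ens <- bootstrapBag(sep$X, sep$y, B = 5, seed = 1)
  neg <- new("SSVMEnsemble", W = -ens@W, b = -ens@b, mu = ens@mu,
             sigma = ens@sigma, seed = ens@seed, redraws = 0L,
             uniqueFraction = ens@uniqueFraction)
  expect_equal(decisionValues(neg, sep$X), -decisionValues(ens, sep$X))
})

test_that("the ensemble mean stabilizes as B grows", {
  sep <- makeSeparable(n = 100, k = 3, seed = 17)
  xstar <- matrix(c(0.5, 0.2, -0.3), 1, 3,
                  dimnames = list(NULL, colnames(sep$X)))
  scoreAt <- function(B, seed)
    decisionValues(bootstrapBag(sep$X, sep$y, B = B, seed = seed), xstar)
  s10 <- vapply(1:8, function(s) scoreAt(10, s), numeric(1))
  s100 <- vapply(1:8, function(s) scoreAt(100, 100 + s), numeric(1))
  expect_lt(sd(s100), sd(s10))
})

test_that("single-class learning sets are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(bootstrapBag(X, rep(1, 10), B = 2), "both classes")
  expect_error(fitSSVM(X, rep(-1, 10)), "both classes")
})
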