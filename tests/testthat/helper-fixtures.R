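## Shared fixtures and independent oracles, all generated in code.

## Linearly separable two-class data with margin.
makeSeparable <- function(n = 60, k = 3, seed = 1, margin = 1) {
  withr::local_seed(seed)
  X <- matrix(rnorm(n * k), n, k)
  y <- rep(c(-1, 1), length.out = n)
  X[, 1] <- X[, 1] * 0.1 + y * (1 + margin)
  colnames(X) <- paste0("V", seq_len(k))
  list(X = X, y = y)
}

## Random soft-margin SSVM instance.
randomInstance <- function(n = 30, k = 5, seed = 1) {
  withr::local_seed(seed)
  X <- matrix(rnorm(n * k), n, k)
  y <- sample(c(-1, 1), n, replace = TRUE)
  if (length(unique(y)) == 1) y[1] <- -y[1]
  X[, 1] <- X[, 1] + 0.8 * y
  cc <- balancedCosts(sum(y > 0), sum(y < 0))
  list(X = X, y = y, ci = ifelse(y > 0, cc$cPos, cc$cNeg),
       cPos = cc$cPos, cNeg = cc$cNeg)
}

## SSVM primal objective of an arbitrary (w, b) via hinge completion.
ssvmObjective <- function(X, y, ci, w, b) {
  f <- drop(X %*% w) + b
  sum(abs(w)) + sum(ci * pmax(0, 1 - y * f))
}

## Independent LP oracle: scipy.optimize.linprog (HiGHS) on the primal
## LP, one python call for a whole batch of instances.
scipyLPObjectives <- function(instances) {
  inp <- tempfile(fileext = ".json")
  outp <- tempfile(fileext = ".json")
  jsonlite::write_json(
    lapply(instances, function(z)
      list(X = z$X, y = z$y, ci = z$ci)),
    inp, digits = NA, auto_unbox = FALSE)
  script <- '
import json, sys
import numpy as np
from scipy.optimize import linprog
objs = []
for d in json.load(open(sys.argv[1])):
    X = np.array(d["X"]); y = np.array(d["y"], float).ravel()
    ci = np.array(d["ci"], float).ravel()
    n, k = X.shape
    A = np.hstack([-X * y[:, None], X * y[:, None],
                   -y[:, None], y[:, None], -np.eye(n)])
    c = np.concatenate([np.ones(2 * k), [0.0, 0.0], ci])
    r = linprog(c, A_ub=A, b_ub=-np.ones(n), method="highs")
    objs.append(r.fun if r.status == 0 else None)
json.dump(objs, open(sys.argv[2], "w"))
'
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", c(sf, inp, outp))
  if (status != 0) stop("python LP oracle failed")
  unlist(jsonlite::read_json(outp))
}

## Planted five-biomarker panel at the recovery-study conditions.
plantedEffects <- function() {
  c(WBC = 0.8, Plt = -0.9, Segs = -0.8, Bands = 1.2, CD64 = 1.0)
}

plantedFixture <- function(seed, nPos = 300, nNeg = 300) {
  eff <- plantedEffects()
  pp <- plantedPanelCohort(names(eff), unname(eff),
                           nPos = nPos, nNeg = nNeg, seed = seed)
  X <- biomarkerMatrix(pp$cohort)
  y <- ifelse(SummarizedExperiment::colData(pp$cohort)$trueGroup < 3,
              1, -1)
  list(X = X, y = y, effects = eff,
       planted = pp$groundTruth$informative, cohort = pp$cohort)
}
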