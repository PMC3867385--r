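#' @include lp.R
NULL

#' Class-balanced slack costs
#'
#' Splits the slack penalty between classes so both contribute the
#' same total cost: `cPos * nPos = cNeg * nNeg` exactly, with
#' `cPos = scale * n / (2 nPos)` and `cNeg = scale * n / (2 nNeg)`.
#' Predictions on separable data are invariant to `scale`.
#'
#' @param nPos,nNeg Class counts (>= 1).
#' @param scale Overall cost scale (> 0, default 1).
#' @return Named list with `cPos` and `cNeg`.
#' @examples
#' balancedCosts(30, 60)  # cPos = 1.5, cNeg = 0.75
#' @export
balancedCosts <- function(nPos, nNeg, scale = 1) {
  stopifnot2(nPos >= 1 && nNeg >= 1, "both classes must be present")
  stopifnot2(scale > 0, "scale must be > 0")
  n <- nPos + nNeg
  list(cPos = scale * n / (2 * nPos), cNeg = scale * n / (2 * nNeg))
}

#' Fit a 1-norm sparse linear SVM
#'
#' Solves
#' `min sum_j |w_j| + cPos sum_{y=+1} xi_i + cNeg sum_{y=-1} xi_i`
#' subject to `y_i (w . x_i + b) >= 1 - xi_i`, `xi >= 0`, as a linear
#' program (bias unpenalized).  The 1-norm penalty drives weights of
#' uninformative biomarkers exactly to zero.
#'
#' @param X Numeric feature matrix (rows = samples), conventionally
#'   standardized.
#' @param y Labels in `{+1, -1}`, both classes present.
#' @param cPos,cNeg Per-sample slack costs; default
#'   [balancedCosts()] at `scale`.
#' @param scale Cost scale used when costs are defaulted.
#' @param mu,sigma Optional standardization parameters to stamp into
#'   the returned model (identity if omitted, for pre-standardized
#'   input).
#' @param method `"dual"` (default; simplex on the 2k+1-row dual with
#'   primal recovery from the multipliers) or `"primal"` (direct).
#' @return List: `model` (a [LinearDecisionFunction]), `xi` slack
#'   vector, `objective`, `iterations`.
#' @export
fitSSVM <- function(X, y, cPos = NULL, cNeg = NULL, scale = 1,
                    mu = NULL, sigma = NULL,
                    method = c("dual", "primal")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  stopifnot2(nrow(X) == length(y), "X and y lengths differ")
  stopifnot2(all(y %in% c(-1, 1)), "labels must be +1/-1")
  nPos <- sum(y > 0); nNeg <- sum(y < 0)
  stopifnot2(nPos >= 1 && nNeg >= 1, "both classes must be present")
  if (is.null(cPos) || is.null(cNeg)) {
    cc <- balancedCosts(nPos, nNeg, scale)
    cPos <- cPos %||% cc$cPos
    cNeg <- cNeg %||% cc$cNeg
  }
  ci <- ifelse(y > 0, cPos, cNeg)
  sol <- ssvmSolveLP(X, y, ci, method = method)
  k <- ncol(X)
  nm <- colnames(X) %||% paste0("V", seq_len(k))
  model <- new("LinearDecisionFunction",
               w = stats::setNames(sol$w, nm), b = sol$b,
               mu = stats::setNames(mu %||% rep(0, k), nm),
               sigma = stats::setNames(sigma %||% rep(1, k), nm))
  list(model = model, xi = sol$xi, objective = sol$objective,
       iterations = sol$iterations)
}

#' Bootstrap-aggregated SSVM ensemble
#'
#' Draws `B` bootstrap resamples of the learning set (same size, with
#' replacement), fits one sparse SVM per resample with class-balanced
#' costs computed on that resample, and aggregates by the mean of the
#' member decision values.  Resamples missing a class are redrawn (the
#' count is kept in the `redraws` slot).
#'
#' @inheritParams fitSSVM
#' @param B Ensemble size (>= 1).
#' @param seed Integer seed (same seed, same ensemble).
#' @param resample Set `FALSE` to fit every member on the full
#'   learning set (degenerate ensemble, useful for reduction tests).
#' @return An [SSVMEnsemble].
#' @export
bootstrapBag <- function(X, y, B = 1000, seed = 1L, scale = 1,
                         mu = NULL, sigma = NULL, resample = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot2(B >= 1, "B must be >= 1")
  stopifnot2(sum(y > 0) >= 1 && sum(y < 0) >= 1,
             "learning set must contain both classes")
  k <- ncol(X)
  nm <- colnames(X) %||% paste0("V", seq_len(k))
  W <- matrix(0, B, k, dimnames = list(NULL, nm))
  bvec <- numeric(B)
  uniq <- numeric(B)
  redraws <- 0L
  withSeed(seed, {
    for (bb in seq_len(B)) {
      if (resample) {
        repeat {
          idx <- sample.int(n, n, replace = TRUE)
          if (length(unique(y[idx])) == 2L) break
          redraws <- redraws + 1L
        }
      } else idx <- seq_len(n)
      uniq[bb] <- length(unique(idx)) / n
      fit <- fitSSVM(X[idx, , drop = FALSE], y[idx], scale = scale)
      W[bb, ] <- fit$model@w
      bvec[bb] <- fit$model@b
    }
  })
  new("SSVMEnsemble", W = W, b = bvec,
      mu = stats::setNames(mu %||% rep(0, k), nm),
      sigma = stats::setNames(sigma %||% rep(1, k), nm),
      seed = as.integer(seed), redraws = redraws,
      uniqueFraction = uniq)
}

## ---------------------------------------------------------------------
## Prediction
## ---------------------------------------------------------------------

#' @rdname decisionValues
#' @export
setMethod("decisionValues", "LinearDecisionFunction",
  function(object, newdata) {
    Xs <- applyStandardization(newdata, object@mu, object@sigma)
    drop(Xs %*% object@w) + object@b
  })

#' @rdname decisionValues
#' @export
setMethod("decisionValues", "SSVMEnsemble",
  function(object, newdata) {
    Xs <- applyStandardization(newdata, object@mu, object@sigma)
    ## the mean of linear members is the linear function of the means
    drop(Xs %*% colMeans(object@W)) + mean(object@b)
  })

#' Predict sepsis diagnoses
#'
#' Decision values are computed by [decisionValues()]; the diagnosis is
#' positive (`+1`) when the score is greater than or equal to zero.
#'
#' @param object A [LinearDecisionFunction] or [SSVMEnsemble].
#' @param newdata Matrix in raw biomarker units (or standardized, if
#'   the model was fitted without standardization parameters).
#' @return List with `score` and `label` vectors.
#' @export
setMethod("predict", "SSVMEnsemble", function(object, newdata) {
  s <- decisionValues(object, newdata)
  list(score = s, label = ifelse(s >= 0, 1, -1))
})

#' @rdname predict-SSVMEnsemble-method
#' @export
setMethod("predict", "LinearDecisionFunction", function(object, newdata) {
  s <- decisionValues(object, newdata)
  list(score = s, label = ifelse(s >= 0, 1, -1))
})

#' @rdname panelWeights
#' @export
setMethod("panelWeights", "LinearDecisionFunction",
          function(object) object@w)

#' @rdname panelWeights
#' @export
setMethod("panelWeights", "SSVMEnsemble",
          function(object) colMeans(object@W))

#' @rdname panelNames
#' @export
setMethod("panelNames", "LinearDecisionFunction",
          function(object) names(object@w))

#' @rdname panelNames
#' @export
setMethod("panelNames", "SSVMEnsemble",
          function(object) colnames(object@W))

setMethod("show", "LinearDecisionFunction", function(object) {
  cat("LinearDecisionFunction over", length(object@w), "biomarkers\n")
  print(round(object@w, 4))
  cat("bias:", round(object@b, 4),
      " nonzero weights:", sum(object@w != 0), "\n")
})

setMethod("show", "SSVMEnsemble", function(object) {
  cat(sprintf("SSVMEnsemble: B = %d members, %d biomarkers (seed %d)\n",
              nrow(object@W), ncol(object@W), object@seed))
  cat("mean weights:\n")
  print(round(colMeans(object@W), 4))
})

## ---------------------------------------------------------------------
## Repeated random divisions
## ---------------------------------------------------------------------

#' Random learning/test divisions
#'
#' Generates `R` independent random divisions with the test set one
#' third of the data.  Divisions are stratified by class by default so
#' small cohorts cannot produce single-class test sets; with
#' `stratified = FALSE`, divisions leaving a single-class test or
#' learning set are redrawn (count attached as an attribute).
#'
#' @param y Labels in `{+1, -1}`.
#' @param R Number of divisions.
#' @param testFraction Fraction held out (default 1/3).
#' @param seed Integer seed.
#' @param stratified Stratify by class (default `TRUE`).
#' @return List of `R` integer vectors of test indices, with attribute
#'   `"redraws"`.
#' @export
makeDivisions <- function(y, R, testFraction = 1 / 3, seed = 1L,
                          stratified = TRUE) {
  n <- length(y)
  pos <- which(y > 0); neg <- which(y < 0)
  stopifnot2(length(pos) >= 2 && length(neg) >= 2,
             "need at least two samples per class")
  redraws <- 0L
  out <- withSeed(seed, {
    lapply(seq_len(R), function(r) {
      if (stratified) {
        np <- max(1L, min(length(pos) - 1L,
                          round(length(pos) * testFraction)))
        nn <- max(1L, min(length(neg) - 1L,
                          round(length(neg) * testFraction)))
        sort(c(sample(pos, np), sample(neg, nn)))
      } else {
        repeat {
          te <- sort(sample.int(n, max(2L, round(n * testFraction))))
          if (length(unique(y[te])) == 2L &&
              length(unique(y[-te])) == 2L) return(te)
          redraws <<- redraws + 1L
        }
      }
    })
  })
  attr(out, "redraws") <- redraws
  out
}

#' Diagnostic performance over repeated random divisions
#'
#' The workhorse evaluation loop: for each of `R` random divisions
#' (test = `testFraction` of the data, stratified), a bagged SSVM
#' ensemble (or a LASSO logistic model) is trained on the learning set
#' and scored on the test set; TPR, TNR, PPV, NPV and ACC are averaged
#' over divisions.  Passing a precomputed `divisions` list makes runs
#' paired across feature subsets.
#'
#' By default standardization is fitted once on the full dataset
#' before splitting (`standardizeOn = "all"`, replicating the original
#' analysis); `"learning"` gives the leakage-safe variant.
#'
#' @param X Raw biomarker matrix (samples x biomarkers, named columns).
#' @param y Labels in `{+1, -1}`.
#' @param features Column names or indices to use (default all).
#' @param R Number of random divisions.
#' @param B Ensemble size per division.
#' @param seed Integer seed.
#' @param scale SSVM cost scale.
#' @param method `"SSVM"` or `"LLR"`.
#' @param divisions Optional list of test-index vectors (from
#'   [makeDivisions()]), reused across calls for paired comparison.
#' @param testFraction Test fraction when `divisions` is `NULL`.
#' @param standardizeOn `"all"` or `"learning"`.
#' @param keepScores Keep a per-division ROC curve in the result.
#' @param lambda LLR penalty; `NULL` selects by 5-fold
#'   cross-validated deviance on each learning set.
#' @return A [PerformanceSummary].
#' @export
repeatedEvaluation <- function(X, y, features = NULL, R = 100, B = 1000,
                               seed = 1L, scale = 1,
                               method = c("SSVM", "LLR"),
                               divisions = NULL, testFraction = 1 / 3,
                               standardizeOn = c("all", "learning"),
                               keepScores = FALSE, lambda = NULL) {
  method <- match.arg(method)
  standardizeOn <- match.arg(standardizeOn)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  stopifnot2(R >= 1, "R must be >= 1")
  seeds <- childSeeds(seed, R + 1L)
  if (is.null(divisions))
    divisions <- makeDivisions(y, R, testFraction, seed = seeds[R + 1L])
  stopifnot2(length(divisions) >= R, "fewer divisions than R")

  measures <- c("TPR", "TNR", "PPV", "NPV", "ACC")
  M <- matrix(NA_real_, R, length(measures),
              dimnames = list(NULL, measures))
  Wm <- matrix(NA_real_, R, ncol(X), dimnames = list(NULL, colnames(X)))
  rocs <- if (keepScores) vector("list", R) else list()

  if (standardizeOn == "all") {
    smAll <- standardizeBiomarkers(X, fittedOn = "all")
  }
  for (r in seq_len(R)) {
    te <- divisions[[r]]
    tr <- setdiff(seq_len(nrow(X)), te)
    if (standardizeOn == "all") {
      mu <- smAll@mu; sigma <- smAll@sigma
      Xtr <- smAll@values[tr, , drop = FALSE]
      Xte <- smAll@values[te, , drop = FALSE]
    } else {
      sm <- standardizeBiomarkers(X[tr, , drop = FALSE],
                                  fittedOn = "learning")
      mu <- sm@mu; sigma <- sm@sigma
      Xtr <- sm@values
      Xte <- applyStandardization(X[te, , drop = FALSE], mu, sigma)
    }
    if (method == "SSVM") {
      ens <- bootstrapBag(Xtr, y[tr], B = B, seed = seeds[r],
                          scale = scale)
      sc <- drop(Xte %*% colMeans(ens@W)) + mean(ens@b)
      Wm[r, ] <- colMeans(ens@W)
    } else {
      fit <- fitLLR(Xtr, y[tr], lambda = lambda, seed = seeds[r])
      sc <- drop(Xte %*% fit@w) + fit@b
      Wm[r, ] <- fit@w
    }
    pred <- ifelse(sc >= 0, 1, -1)
    M[r, ] <- classMeasures(confusionCounts(y[te], pred))
    if (keepScores) rocs[[r]] <- rocCurve(sc, y[te])
  }

  nUnd <- colSums(is.na(M))
  new("PerformanceSummary",
      means = colMeans(M, na.rm = TRUE),
      sds = apply(M, 2, sd, na.rm = TRUE),
      nUndefined = stats::setNames(as.integer(nUnd), measures),
      R = as.integer(R), features = colnames(X), method = method,
      weightMean = colMeans(Wm),
      weightSE = apply(Wm, 2, sd) / sqrt(R),
      rocs = rocs)
}

#' Performance summary as a one-row table
#' @param x A [PerformanceSummary].
#' @return A data.frame in report shape (method, mean and SD per
#'   measure).
#' @export
performanceTable <- function(x) {
  data.frame(Method = x@method,
             as.list(round(x@means, 3)),
             as.list(stats::setNames(round(x@sds, 3),
                                     paste0(names(x@sds), ".sd"))),
             check.names = FALSE)
}

setMethod("show", "PerformanceSummary", function(object) {
  cat(sprintf("PerformanceSummary (%s, R = %d, features: %s)\n",
              object@method, object@R,
              paste(object@features, collapse = ", ")))
  m <- rbind(mean = object@means, sd = object@sds)
  print(round(m, 3))
  if (any(object@nUndefined > 0))
    cat("divisions with undefined measures:",
        paste(names(object@nUndefined)[object@nUndefined > 0],
              object@nUndefined[object@nUndefined > 0],
              collapse = ", "), "\n")
})
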