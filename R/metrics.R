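#' @include AllClasses.R
NULL

#' Confusion counts
#'
#' @param yTrue,yPred Label vectors in `{+1, -1}` of equal length
#'   (`+1` = positive).
#' @return Named integer vector `tp`, `fp`, `tn`, `fn`.
#' @export
confusionCounts <- function(yTrue, yPred) {
  stopifnot2(length(yTrue) == length(yPred),
             "yTrue and yPred lengths differ")
  stopifnot2(all(yTrue %in% c(-1, 1)) && all(yPred %in% c(-1, 1)),
             "labels must be +1/-1")
  c(tp = sum(yTrue > 0 & yPred > 0),
    fp = sum(yTrue < 0 & yPred > 0),
    tn = sum(yTrue < 0 & yPred < 0),
    fn = sum(yTrue > 0 & yPred < 0))
}

#' Diagnostic performance measures
#'
#' `TPR = tp/(tp+fn)`, `TNR = tn/(tn+fp)`, `PPV = tp/(tp+fp)`,
#' `NPV = tn/(tn+fn)`, `ACC = (tp+tn)/n`.  A zero denominator yields
#' `NA` (propagated, never silently zero).
#'
#' @param counts Named counts from [confusionCounts()].
#' @return Named numeric vector of the five measures.
#' @examples
#' classMeasures(c(tp = 5, fp = 1, tn = 8, fn = 2))
#' @export
classMeasures <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  n <- tp + fp + tn + fn
  stopifnot2(n > 0, "no samples")
  rat <- function(a, b) if (b == 0) NA_real_ else a / b
  c(TPR = rat(tp, tp + fn), TNR = rat(tn, tn + fp),
    PPV = rat(tp, tp + fp), NPV = rat(tn, tn + fn),
    ACC = (tp + tn) / n)
}

#' ROC curve of a score vector
#'
#' Traces TPR against FPR as the decision threshold sweeps over the
#' distinct scores, predicting positive when `score >= threshold`
#' (the same inclusive convention as [predict()], so the deployed
#' operating point lies exactly on the curve).  AUC by the trapezoid
#' rule.
#'
#' @param scores Numeric decision values.
#' @param yTrue Labels in `{+1, -1}`, both classes present.
#' @return List with `fpr`, `tpr` (from (0,0) to (1,1)),
#'   `thresholds`, and `auc`.
#' @export
rocCurve <- function(scores, yTrue) {
  nPos <- sum(yTrue > 0); nNeg <- sum(yTrue < 0)
  stopifnot2(nPos > 0 && nNeg > 0, "both classes must be present")
  if (length(unique(scores)) == 1L) {
    warning("constant scores; ROC is the chance diagonal")
    return(list(fpr = c(0, 1), tpr = c(0, 1),
                thresholds = c(Inf, unique(scores)), auc = 0.5))
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yp <- yTrue[ord] > 0
  ## at threshold s[i] (inclusive), everything with score >= s[i] is +
  tps <- cumsum(yp); fps <- cumsum(!yp)
  last <- !duplicated(s, fromLast = TRUE) # last index of each tie block
  tpr <- c(0, tps[last] / nPos)
  fpr <- c(0, fps[last] / nNeg)
  list(fpr = fpr, tpr = tpr,
       thresholds = c(Inf, s[last]),
       auc = sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2))
}

## TPR of a single curve at arbitrary FPR values (linear interpolation
## between ROC vertices; vertical segments evaluate to their top).
.rocAt <- function(curve, fprOut) {
  keep <- !duplicated(curve$fpr, fromLast = TRUE) # max tpr per fpr
  approx(curve$fpr[keep], curve$tpr[keep], xout = fprOut,
         method = "linear", rule = 2, ties = "ordered")$y
}

#' Vertically averaged ROC curve with SD band
#'
#' Interpolates each member curve onto a common FPR grid and reports
#' the per-grid-point mean and standard deviation of TPR, plus the
#' mean member AUC -- the summary used to display an ROC averaged over
#' repeated random divisions with a shaded SD band.
#'
#' @param curves List of curves from [rocCurve()] (R >= 2 for an SD).
#' @param fprGrid FPR grid (default 101 points on `[0, 1]`).
#' @return An [ROCCurve].
#' @export
averageRoc <- function(curves, fprGrid = seq(0, 1, length.out = 101)) {
  stopifnot2(length(curves) >= 2, "need at least 2 curves for an SD")
  Tp <- vapply(curves, .rocAt, numeric(length(fprGrid)),
               fprOut = fprGrid)
  new("ROCCurve",
      fprGrid = fprGrid,
      tprMean = rowMeans(Tp),
      tprSd = apply(Tp, 1, sd),
      aucMean = mean(vapply(curves, `[[`, numeric(1), "auc")),
      R = length(curves))
}

setMethod("show", "ROCCurve", function(object) {
  cat(sprintf("ROCCurve averaged over %d divisions; mean AUC %.3f\n",
              object@R, object@aucMean))
})

#' Grid representation of an averaged ROC curve
#' @param x An [ROCCurve].
#' @return data.frame `fpr`, `tprMean`, `tprSd`.
#' @export
rocTable <- function(x)
  data.frame(fpr = x@fprGrid, tprMean = x@tprMean, tprSd = x@tprSd)

#' Univariate biomarker screening p-values
#'
#' Two-sample test of each biomarker between the septic and nonseptic
#' groups: Welch's t-test by default, or the Mann-Whitney test.  A
#' biomarker constant in both groups is reported with `p = 1` and
#' flagged degenerate.
#'
#' @param X Biomarker matrix (samples x biomarkers).
#' @param y Labels in `{+1, -1}`, each group with >= 2 samples.
#' @param test `"welch"` or `"wilcoxon"`.
#' @return data.frame with `biomarker`, `statistic`, `p.value`,
#'   `test`, `degenerate`.
#' @export
univariatePvalues <- function(X, y, test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  X <- as.matrix(X)
  stopifnot2(sum(y > 0) >= 2 && sum(y < 0) >= 2,
             "each group needs >= 2 samples")
  nm <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  res <- lapply(seq_len(ncol(X)), function(j) {
    a <- X[y > 0, j]; b <- X[y < 0, j]
    if (sd(a) == 0 && sd(b) == 0) {
      return(data.frame(biomarker = nm[j], statistic = 0, p.value = 1,
                        test = test, degenerate = TRUE))
    }
    h <- if (test == "welch") stats::t.test(a, b)
         else suppressWarnings(stats::wilcox.test(a, b))
    data.frame(biomarker = nm[j], statistic = unname(h$statistic),
               p.value = h$p.value, test = test, degenerate = FALSE)
  })
  do.call(rbind, res)
}

#' Exhaustive all-subsets classifier validation
#'
#' Evaluates the bagged SSVM on *every* subset of the biomarkers for
#' each requested size k, all on the same `R` random divisions, and
#' ranks the canonical-correlation-selected subset against the full
#' enumeration under each performance measure (rank 1 = highest mean).
#' This turns the "is the selected panel really the best?" display
#' into a stable, testable rank.
#'
#' @param X Raw biomarker matrix (samples x biomarkers, p <= 12).
#' @param y Labels in `{+1, -1}`.
#' @param kRange Subset sizes to sweep.
#' @param R,B Divisions and ensemble size (reduced values are
#'   customary here; the sweep fits `sum_k C(p,k) * R * B` models).
#' @param seed Integer seed.
#' @param scale SSVM cost scale.
#' @param path Optional precomputed [SelectionPath]; computed from
#'   `(X, y)` if omitted.
#' @return A [ValidationSweep].
#' @export
exhaustiveValidation <- function(X, y, kRange = seq_len(ncol(X)),
                                 R = 5, B = 10, seed = 1L, scale = 1,
                                 path = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot2(p <= 12, "exhaustive validation is limited to p <= 12")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
  kRange <- sort(unique(as.integer(kRange)))
  if (is.null(path)) path <- bestSubsets(X, y, kRange)
  seeds <- childSeeds(seed, 2L)
  divisions <- makeDivisions(y, R, seed = seeds[1])
  measures <- c("TPR", "TNR", "PPV", "NPV", "ACC")
  results <- list()
  ccaRanks <- matrix(NA_integer_, length(kRange), length(measures),
                     dimnames = list(paste0("k", kRange), measures))
  for (i in seq_along(kRange)) {
    k <- kRange[i]
    combos <- combn(p, k)
    perf <- matrix(NA_real_, ncol(combos), length(measures),
                   dimnames = list(NULL, measures))
    psd <- matrix(NA_real_, ncol(combos), length(measures),
                  dimnames = list(NULL, paste0(measures, ".sd")))
    labels <- character(ncol(combos))
    for (q in seq_len(ncol(combos))) {
      S <- combos[, q]
      ps <- repeatedEvaluation(X, y, features = S, R = R, B = B,
                               seed = seeds[2], scale = scale,
                               divisions = divisions)
      perf[q, ] <- ps@means
      psd[q, ] <- ps@sds
      labels[q] <- paste(colnames(X)[S], collapse = ",")
    }
    sel <- selectedSubset(path, k)
    qSel <- which(vapply(seq_len(ncol(combos)), function(q)
      identical(sort(combos[, q]), sort(sel)), logical(1)))
    for (m in measures) {
      rk <- rank(-perf[, m], ties.method = "min", na.last = "keep")
      ccaRanks[i, m] <- rk[qSel]
    }
    results[[paste0("k", k)]] <- data.frame(subset = labels, perf, psd,
                                            stringsAsFactors = FALSE,
                                            check.names = FALSE)
  }
  new("ValidationSweep", results = results, ccaRanks = ccaRanks,
      kRange = kRange, R = as.integer(R), B = as.integer(B))
}

setMethod("show", "ValidationSweep", function(object) {
  cat("ValidationSweep over k =",
      paste(object@kRange, collapse = ", "),
      sprintf("(R = %d, B = %d)\n", object@R, object@B))
  cat("rank of the CCA-selected subset per measure:\n")
  print(object@ccaRanks)
})
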