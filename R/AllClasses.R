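#' @include AllGenerics.R
NULL

#' The ten hematological biomarkers, in canonical order
#'
#' Age (day of life, days), WBC (x10^3/uL), Hgb (g/dL), Hct (%%),
#' Plt (x10^3/uL), Segs (%% of WBC), Bands (%% of WBC), Lymph (%% of WBC),
#' Mono (%% of WBC), and the neutrophil CD64 index (unitless).
#'
#' @export
BIOMARKERS <- c("Age", "WBC", "Hgb", "Hct", "Plt",
                "Segs", "Bands", "Lymph", "Mono", "CD64")

## Biomarkers generated on a log scale (right-skewed marginals).
LOG_SCALE_BIOMARKERS <- c("WBC", "Plt", "Bands", "CD64")

## ---------------------------------------------------------------------
## CohortSpec
## ---------------------------------------------------------------------

#' Specification of a synthetic two-group sepsis cohort
#'
#' Describes group sizes, per-group marginal means/SDs for each
#' biomarker (raw measurement units), a target Pearson correlation
#' matrix, the set of informative biomarkers (those whose group means
#' differ), the fraction of septic evaluations carrying a positive
#' blood culture, and the RNG seed.  Construct with [cohortSpec()] or
#' [defaultCohortSpec()].
#'
#' @slot nPos,nNeg Septic / nonseptic group sizes.
#' @slot biomarkerNames Ordered biomarker names (length p).
#' @slot meanPos,meanNeg,sdPos,sdNeg Named per-group marginal moments.
#' @slot corr Target p x p Pearson correlation matrix (positive definite).
#' @slot informative Integer indices of biomarkers with group-mean shifts.
#' @slot logScale Named logical: biomarkers generated as lognormal.
#' @slot culturePosFraction Fraction of septic evaluations drawn
#'   culture-positive.
#' @slot seed Integer RNG seed.
#' @export
setClass("CohortSpec",
  representation(nPos = "integer", nNeg = "integer",
                 biomarkerNames = "character",
                 meanPos = "numeric", meanNeg = "numeric",
                 sdPos = "numeric", sdNeg = "numeric",
                 corr = "matrix", informative = "integer",
                 logScale = "logical",
                 culturePosFraction = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
  p <- length(object@biomarkerNames)
  msg <- character()
  if (object@nPos < 1L || object@nNeg < 1L)
    msg <- c(msg, "nPos and nNeg must both be >= 1")
  for (s in c("meanPos", "meanNeg", "sdPos", "sdNeg", "logScale"))
    if (length(slot(object, s)) != p)
      msg <- c(msg, sprintf("%s must have one entry per biomarker", s))
  if (any(object@sdPos <= 0) || any(object@sdNeg <= 0))
    msg <- c(msg, "all marginal SDs must be > 0")
  if (!isTRUE(all.equal(dim(object@corr), c(p, p))))
    msg <- c(msg, "corr must be p x p")
  else {
    if (max(abs(object@corr - t(object@corr))) > 1e-12)
      msg <- c(msg, "corr must be symmetric")
    if (max(abs(diag(object@corr) - 1)) > 1e-12)
      msg <- c(msg, "corr must have a unit diagonal")
    ev <- tryCatch(min(eigen(object@corr, symmetric = TRUE,
                             only.values = TRUE)$values),
                   error = function(e) -Inf)
    if (!(ev > 0))
      msg <- c(msg, sprintf(
        "corr must be positive definite (smallest eigenvalue %.3g <= 0)", ev))
  }
  noninf <- setdiff(seq_len(p), object@informative)
  if (length(noninf) &&
      any(object@meanPos[noninf] != object@meanNeg[noninf]))
    msg <- c(msg, "meanPos must equal meanNeg outside the informative set")
  if (object@culturePosFraction < 0 || object@culturePosFraction > 1)
    msg <- c(msg, "culturePosFraction must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------
## SepsisCohort
## ---------------------------------------------------------------------

#' A cohort of sepsis evaluations
#'
#' Extends `SummarizedExperiment`: the `"biomarkers"` assay holds the
#' p x n matrix of biomarker values (rows = biomarkers, columns =
#' evaluations), and `colData` carries the per-evaluation clinical
#' fields: `dayOfLife`, the score-rule inputs `anc`, `abc` (cells/mm^3),
#' `itRatio`, `plt` (x10^3/uL), `culturePositive`, the generator's
#' `trueGroup` (synthetic cohorts), and, after [makeLabels()], the
#' assigned `group` and the `label` in `{+1, -1}`.
#'
#' @export
setClass("SepsisCohort", contains = "SummarizedExperiment")

setValidity("SepsisCohort", function(object) {
  msg <- character()
  if (!"biomarkers" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'biomarkers' is required")
  needed <- c("anc", "abc", "itRatio", "plt", "culturePositive")
  have <- colnames(SummarizedExperiment::colData(object))
  miss <- setdiff(needed, have)
  if (length(miss))
    msg <- c(msg, paste("missing colData columns:",
                        paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------
## CriteriaThresholds
## ---------------------------------------------------------------------

#' Thresholds for the hematologic 2-of-4 sepsis score
#'
#' The four criteria are: ANC outside `[ancLow, ancHigh]` (cells/mm^3);
#' ABC `>= abcMin` (cells/mm^3); IT-ratio `>= itRatioMin`; platelet
#' count `<= pltMax` (x10^3/uL).  An evaluation meeting two or more
#' criteria has a positive sepsis score.  Construct with
#' [criteriaThresholds()], whose defaults are implementer-chosen values
#' from the neonatal hematologic-scoring literature.
#'
#' @slot ancLow,ancHigh,abcMin Cell counts per mm^3.
#' @slot itRatioMin Dimensionless, in (0, 1).
#' @slot pltMax Platelets, x10^3/uL.
#' @export
setClass("CriteriaThresholds",
  representation(ancLow = "numeric", ancHigh = "numeric",
                 abcMin = "numeric", itRatioMin = "numeric",
                 pltMax = "numeric"))

setValidity("CriteriaThresholds", function(object) {
  msg <- character()
  if (!(object@ancLow < object@ancHigh))
    msg <- c(msg, "ancLow must be < ancHigh")
  vals <- c(object@ancLow, object@ancHigh, object@abcMin, object@pltMax)
  if (any(vals <= 0)) msg <- c(msg, "all thresholds must be > 0")
  if (object@itRatioMin <= 0 || object@itRatioMin >= 1)
    msg <- c(msg, "itRatioMin must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------
## StandardizedMatrix
## ---------------------------------------------------------------------

#' A standardized biomarker matrix with its standardization parameters
#'
#' Holds `(X - mu) / sigma` column-wise together with the per-biomarker
#' means `mu` and SDs `sigma` (original units) needed to apply the same
#' affine map to new samples, and a provenance tag saying whether the
#' parameters were fitted on all data or on a learning set only.
#'
#' @slot values n x p standardized matrix (dimensionless).
#' @slot mu,sigma Named numeric, original units; `sigma > 0`.
#' @slot fittedOn `"all"` or `"learning"`.
#' @export
setClass("StandardizedMatrix",
  representation(values = "matrix", mu = "numeric", sigma = "numeric",
                 fittedOn = "character"))

setValidity("StandardizedMatrix", function(object) {
  msg <- character()
  if (any(object@sigma <= 0)) msg <- c(msg, "sigma must be > 0")
  if (length(object@mu) != ncol(object@values) ||
      length(object@sigma) != ncol(object@values))
    msg <- c(msg, "mu/sigma length must match the number of columns")
  if (!object@fittedOn %in% c("all", "learning"))
    msg <- c(msg, "fittedOn must be 'all' or 'learning'")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------
## LinearDecisionFunction
## ---------------------------------------------------------------------

#' A linear sepsis score
#'
#' The decision function `Score(x) = w . xtilde + b`, where `xtilde`
#' is the raw biomarker vector standardized by the stored `mu`/`sigma`.
#' A diagnosis is positive when the score is greater than or equal to
#' zero.
#'
#' @slot w Named weights (standardized scale).
#' @slot b Bias.
#' @slot mu,sigma Standardization parameters (raw units), same names
#'   and order as `w`.
#' @export
setClass("LinearDecisionFunction",
  representation(w = "numeric", b = "numeric",
                 mu = "numeric", sigma = "numeric"))

setValidity("LinearDecisionFunction", function(object) {
  msg <- character()
  if (!all(is.finite(object@w)) || !is.finite(object@b))
    msg <- c(msg, "weights and bias must be finite")
  k <- length(object@w)
  if (length(object@mu) != k || length(object@sigma) != k)
    msg <- c(msg, "mu/sigma must match the weight vector length")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------
## SSVMEnsemble
## ---------------------------------------------------------------------

#' A bootstrap-aggregated ensemble of sparse linear SVMs
#'
#' `B` member classifiers fitted on bootstrap resamples of a learning
#' set; the ensemble decision value is the mean of the member decision
#' values, thresholded at zero (inclusive) for a positive diagnosis.
#' Member weights are stored row-wise in `W`.
#'
#' @slot W B x k matrix of member weights (standardized scale).
#' @slot b Length-B member biases.
#' @slot mu,sigma Shared standardization parameters (raw units).
#' @slot seed Integer seed the ensemble was built from.
#' @slot redraws Number of bootstrap resamples redrawn because they
#'   missed a class.
#' @slot uniqueFraction Per-member fraction of distinct learning
#'   samples in the resample (expected about `1 - (1 - 1/n)^n`).
#' @export
setClass("SSVMEnsemble",
  representation(W = "matrix", b = "numeric",
                 mu = "numeric", sigma = "numeric",
                 seed = "integer", redraws = "integer",
                 uniqueFraction = "numeric"))

setValidity("SSVMEnsemble", function(object) {
  msg <- character()
  if (nrow(object@W) < 1L) msg <- c(msg, "ensemble must have B >= 1 members")
  if (length(object@b) != nrow(object@W))
    msg <- c(msg, "one bias per member required")
  if (length(object@mu) != ncol(object@W) ||
      length(object@sigma) != ncol(object@W))
    msg <- c(msg, "mu/sigma must match the feature count")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------
## SelectionPath
## ---------------------------------------------------------------------

#' Best biomarker subsets per size, with enter/leave annotations
#'
#' For each subset size k, the exhaustively best subset by canonical
#' correlation with the label, the correlation itself, and the set
#' differences against the best (k-1)-subset, plus the greedy Forward
#' Selection order for comparison.
#'
#' @slot table `data.frame` with columns `k`, `rho`, `subset`
#'   (list of index vectors), `enter`, `leave` (comma-separated names).
#' @slot fsOrder Forward Selection's ordered biomarker names.
#' @slot biomarkerNames Candidate biomarker names.
#' @export
setClass("SelectionPath",
  representation(table = "data.frame", fsOrder = "character",
                 biomarkerNames = "character"))

## ---------------------------------------------------------------------
## PerformanceSummary
## ---------------------------------------------------------------------

#' Diagnostic performance over repeated random divisions
#'
#' Mean and SD of TPR, TNR, PPV, NPV and ACC over R random
#' learning/test divisions, together with the mean ensemble weights and
#' their standard errors across divisions.  Measures with a zero
#' denominator in some division are excluded from that measure's
#' mean/SD and counted in `nUndefined`.
#'
#' @slot means,sds Named numeric over the five measures.
#' @slot nUndefined Named integer: divisions excluded per measure.
#' @slot R Number of divisions.
#' @slot features Biomarker names used.
#' @slot method `"SSVM"` or `"LLR"`.
#' @slot weightMean,weightSE Mean and SE of weights across divisions.
#' @slot rocs List of per-division ROC curves (possibly empty).
#' @export
setClass("PerformanceSummary",
  representation(means = "numeric", sds = "numeric",
                 nUndefined = "integer", R = "integer",
                 features = "character", method = "character",
                 weightMean = "numeric", weightSE = "numeric",
                 rocs = "list"))

setValidity("PerformanceSummary", function(object) {
  msg <- character()
  ok <- is.na(object@means) | (object@means >= 0 & object@means <= 1)
  if (!all(ok)) msg <- c(msg, "means must lie in [0, 1]")
  if (any(object@sds < 0, na.rm = TRUE)) msg <- c(msg, "sds must be >= 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------
## ROCCurve (vertically averaged)
## ---------------------------------------------------------------------

#' A vertically averaged ROC curve
#'
#' Member curves are interpolated onto a common FPR grid; the slots
#' hold the per-grid-point mean and SD of TPR and the mean of the
#' member AUCs.
#'
#' @slot fprGrid FPR grid in `[0, 1]`.
#' @slot tprMean,tprSd TPR mean/SD at each grid point.
#' @slot aucMean Mean member AUC.
#' @slot R Number of member curves.
#' @export
setClass("ROCCurve",
  representation(fprGrid = "numeric", tprMean = "numeric",
                 tprSd = "numeric", aucMean = "numeric", R = "integer"))

setValidity("ROCCurve", function(object) {
  msg <- character()
  if (any(diff(object@tprMean) < -1e-9))
    msg <- c(msg, "tprMean must be nondecreasing along the FPR grid")
  if (object@aucMean < 0 || object@aucMean > 1)
    msg <- c(msg, "aucMean must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------
## ValidationSweep
## ---------------------------------------------------------------------

#' Exhaustive all-subsets validation results
#'
#' For each subset size k, performance summaries for every C(p, k)
#' subset (all evaluated on the same R random divisions), and the rank
#' of the canonical-correlation-selected subset under each measure
#' (rank 1 = best mean).
#'
#' @slot results Named list (one element per k) of `data.frame`s with a
#'   subset column and the five measure means.
#' @slot ccaRanks Matrix k x measure of the CCA subset's ranks.
#' @slot kRange Subset sizes evaluated.
#' @slot R,B Divisions and ensemble size used.
#' @export
setClass("ValidationSweep",
  representation(results = "list", ccaRanks = "matrix",
                 kRange = "integer", R = "integer", B = "integer"))
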