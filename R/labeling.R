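#' @include AllClasses.R
NULL

#' Thresholds for the hematologic sepsis score
#'
#' Defaults are implementer-chosen values from the neonatal
#' hematologic-scoring literature: ANC abnormal outside
#' 1750--25000 cells/mm^3, ABC >= 2000 cells/mm^3, IT-ratio >= 0.2,
#' platelets <= 150 x10^3/uL.  All five are configuration, surfaced in
#' every report header written by [runPipeline()].
#'
#' @param ancLow,ancHigh ANC normal range bounds (cells/mm^3).
#' @param abcMin ABC criterion threshold (cells/mm^3).
#' @param itRatioMin IT-ratio criterion threshold.
#' @param pltMax Platelet criterion threshold (x10^3/uL).
#' @return A [CriteriaThresholds].
#' @export
criteriaThresholds <- function(ancLow = 1750, ancHigh = 25000,
                               abcMin = 2000, itRatioMin = 0.2,
                               pltMax = 150) {
  obj <- new("CriteriaThresholds", ancLow = ancLow, ancHigh = ancHigh,
             abcMin = abcMin, itRatioMin = itRatioMin, pltMax = pltMax)
  methods::validObject(obj)
  obj
}

## Vectorized count of criteria met (inclusive boundary convention).
.criteriaMet <- function(anc, abc, itRatio, plt, th) {
  as.integer((anc < th@ancLow | anc > th@ancHigh) +
             (abc >= th@abcMin) +
             (itRatio >= th@itRatioMin) +
             (plt <= th@pltMax))
}

## Extract score-rule inputs from a cohort or plain data.frame.
.scoreInputs <- function(x) {
  if (methods::is(x, "SepsisCohort"))
    x <- as.data.frame(SummarizedExperiment::colData(x))
  stopifnot2(all(c("anc", "abc", "itRatio", "plt") %in% colnames(x)),
             "score inputs anc, abc, itRatio, plt are required")
  x
}

#' Hematologic 2-of-4 sepsis score
#'
#' Counts how many of the four laboratory criteria each evaluation
#' meets -- ANC outside the normal range, elevated ABC, elevated
#' IT-ratio, low platelets -- and declares the score positive when two
#' or more are met.  All comparisons are inclusive.
#'
#' @param x A [SepsisCohort] or a data.frame with columns `anc`,
#'   `abc`, `itRatio`, `plt`.
#' @param thresholds A [CriteriaThresholds].
#' @return A data.frame with integer `criteriaMet` (0--4) and logical
#'   `positive`.  Records with missing or non-finite score inputs get
#'   `NA` in both columns (flagged for exclusion, never silently
#'   scored).
#' @examples
#' df <- data.frame(anc = 1000, abc = 2500, itRatio = 0.25, plt = 300)
#' hematologicScore(df)  # 3 criteria met -> positive
#' @export
hematologicScore <- function(x, thresholds = criteriaThresholds()) {
  d <- .scoreInputs(x)
  ok <- is.finite(d$anc) & is.finite(d$abc) &
    is.finite(d$itRatio) & is.finite(d$plt)
  met <- rep(NA_integer_, nrow(d))
  met[ok] <- .criteriaMet(d$anc[ok], d$abc[ok], d$itRatio[ok],
                          d$plt[ok], thresholds)
  data.frame(criteriaMet = met, positive = met >= 2L,
             row.names = rownames(d))
}

#' Assign each evaluation to one of the three outcome groups
#'
#' Group 1 (culture-proven sepsis) iff the blood culture is positive;
#' otherwise group 2 (clinical sepsis) iff the hematologic score is
#' positive; otherwise group 3 (nonseptic).  The partition is
#' exhaustive and exclusive.
#'
#' @inheritParams hematologicScore
#' @return Integer vector in `{1, 2, 3}`.
#' @export
assignGroup <- function(x, thresholds = criteriaThresholds()) {
  d <- .scoreInputs(x)
  stopifnot2("culturePositive" %in% colnames(d),
             "culture result is required")
  stopifnot2(!anyNA(d$culturePositive), "culture result must be known")
  sc <- hematologicScore(d, thresholds)
  stopifnot2(!anyNA(sc$positive[!d$culturePositive]),
             "cannot assign groups with missing score inputs; run excludeIncomplete() first")
  ifelse(d$culturePositive, 1L, ifelse(sc$positive, 2L, 3L))
}

#' Construct septic/nonseptic labels from culture and score
#'
#' Runs [assignGroup()] and attaches both the group and the class
#' label (`+1` for groups 1 and 2, `-1` for group 3) to the cohort.
#'
#' @inheritParams hematologicScore
#' @return The cohort with `group` and `label` columns in `colData`.
#' @export
makeLabels <- function(x, thresholds = criteriaThresholds()) {
  stopifnot2(methods::is(x, "SepsisCohort"), "x must be a SepsisCohort")
  stopifnot2(ncol(x) > 0, "empty cohort")
  grp <- assignGroup(x, thresholds)
  y <- ifelse(grp <= 2L, 1, -1)
  if (length(unique(y)) < 2L)
    stop("labeling produced a single class; downstream classifiers are undefined")
  SummarizedExperiment::colData(x)$group <- grp
  SummarizedExperiment::colData(x)$label <- y
  x
}

#' Exclude incomplete evaluations (and optionally CD64 outliers)
#'
#' Keeps evaluations with all biomarkers, all score-rule inputs and a
#' known culture result.  An optional CD64 cutoff additionally excludes
#' extreme values (disabled by default; the analysis this mirrors
#' removed a single manually identified evaluation).
#'
#' @param x A [SepsisCohort].
#' @param cd64Cutoff Numeric cutoff for the CD64 index, or `NULL`
#'   (default) to disable outlier exclusion.
#' @return List with `kept` (a [SepsisCohort]) and `excluded`
#'   (data.frame `evalId`, `reason` with machine-readable reasons like
#'   `"missing:CD64"` or `"outlier:CD64"`).
#' @export
excludeIncomplete <- function(x, cd64Cutoff = NULL) {
  stopifnot2(methods::is(x, "SepsisCohort"), "x must be a SepsisCohort")
  X <- biomarkerMatrix(x)
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  ids <- colnames(x) %||% as.character(seq_len(ncol(x)))
  reason <- rep(NA_character_, ncol(x))
  for (j in colnames(X)) {
    bad <- is.na(reason) & !is.finite(X[, j])
    reason[bad] <- paste0("missing:", j)
  }
  for (j in c("anc", "abc", "itRatio", "plt")) {
    bad <- is.na(reason) & !is.finite(cd[[j]])
    reason[bad] <- paste0("missing:", j)
  }
  bad <- is.na(reason) & is.na(cd$culturePositive)
  reason[bad] <- "missing:culture"
  if (!is.null(cd64Cutoff)) {
    bad <- is.na(reason) & X[, "CD64"] > cd64Cutoff
    reason[bad] <- "outlier:CD64"
  }
  keep <- is.na(reason)
  list(kept = x[, keep],
       excluded = data.frame(evalId = ids[!keep],
                             reason = reason[!keep],
                             stringsAsFactors = FALSE))
}
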