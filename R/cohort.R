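#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------
## Default study conditions
## ---------------------------------------------------------------------

## Pooled marginal means/SDs (raw units).  WBC, Plt, Segs, Bands and
## CD64 use the published pooled values for the NICU cohort this
## generator emulates; the remaining five are implementer-chosen
## NICU-plausible defaults (documented in the methods vignette).
.defaultMarginals <- function() {
  data.frame(
    row.names = BIOMARKERS,
    mean = c(Age = 18, WBC = 14.04, Hgb = 15.5, Hct = 47,
             Plt = 231.37, Segs = 39.64, Bands = 7.92,
             Lymph = 35, Mono = 8, CD64 = 2.96)[BIOMARKERS],
    sd = c(Age = 6, WBC = 8.70, Hgb = 2.5, Hct = 7,
           Plt = 103.38, Segs = 17.25, Bands = 9.61,
           Lymph = 12, Mono = 4, CD64 = 2.42)[BIOMARKERS])
}

## Default standardized group-mean differences (septic minus nonseptic,
## in within-group SD units) for the five informative panel biomarkers.
## Signs follow the classifier's weight pattern (Bands, CD64, WBC up in
## sepsis; Plt, Segs down), with Bands the strongest single marker.
.defaultEffects <- function() {
  c(WBC = 0.8, Plt = -0.9, Segs = -0.8, Bands = 1.2, CD64 = 1.0)
}

#' Default within-group biomarker correlation matrix
#'
#' A hematologically plausible positive-definite target: strong
#' Hgb-Hct coupling, the Segs-Lymph differential trade-off, and a
#' Bands-CD64 correlation exceeding the Bands-Plt correlation in
#' magnitude.
#'
#' @return A 10 x 10 correlation matrix over [BIOMARKERS].
#' @export
defaultCorrelation <- function() {
  nm <- BIOMARKERS
  R <- diag(10)
  dimnames(R) <- list(nm, nm)
  set_ <- function(a, b, v) { R[a, b] <<- v; R[b, a] <<- v }
  set_("Hgb", "Hct", 0.85)
  set_("WBC", "Segs", 0.35); set_("WBC", "Bands", 0.30)
  set_("WBC", "Lymph", 0.15); set_("WBC", "Mono", 0.10)
  set_("Segs", "Lymph", -0.55); set_("Segs", "Mono", -0.15)
  set_("Lymph", "Mono", -0.10)
  set_("Bands", "CD64", 0.45); set_("Bands", "Plt", -0.10)
  set_("CD64", "Plt", -0.15); set_("Bands", "Segs", -0.10)
  set_("Bands", "Lymph", -0.15); set_("CD64", "WBC", 0.15)
  set_("CD64", "Segs", 0.05); set_("Plt", "WBC", 0.10)
  R
}

## ---------------------------------------------------------------------
## CohortSpec constructors
## ---------------------------------------------------------------------

#' Construct a cohort specification
#'
#' @param nPos,nNeg Septic / nonseptic group sizes.
#' @param meanPos,meanNeg,sdPos,sdNeg Named per-biomarker marginal
#'   moments in raw units.
#' @param corr Target Pearson correlation matrix (positive definite).
#' @param informative Indices (or names) of biomarkers whose group
#'   means differ.
#' @param logScale Named logical; `TRUE` for biomarkers generated as
#'   lognormal (right-skewed).  Defaults to WBC, Plt, Bands, CD64.
#' @param culturePosFraction Fraction of septic evaluations drawn
#'   culture-positive (so both culture-proven and clinical-sepsis
#'   groups exist).
#' @param seed Integer RNG seed.
#' @return A validated [CohortSpec].
#' @export
cohortSpec <- function(nPos, nNeg, meanPos, meanNeg, sdPos, sdNeg,
                       corr, informative,
                       logScale = NULL,
                       culturePosFraction = 0.5, seed = 1L) {
  nm <- names(meanPos)
  stopifnot2(!is.null(nm), "meanPos must be a named vector")
  if (is.character(informative)) informative <- match(informative, nm)
  if (is.null(logScale))
    logScale <- stats::setNames(nm %in% LOG_SCALE_BIOMARKERS, nm)
  if (is.null(dimnames(corr))) dimnames(corr) <- list(nm, nm)
  obj <- new("CohortSpec",
             nPos = as.integer(nPos), nNeg = as.integer(nNeg),
             biomarkerNames = nm,
             meanPos = meanPos, meanNeg = meanNeg[nm],
             sdPos = sdPos[nm], sdNeg = sdNeg[nm],
             corr = corr[nm, nm],
             informative = sort(as.integer(informative)),
             logScale = logScale[nm],
             culturePosFraction = culturePosFraction,
             seed = as.integer(seed))
  methods::validObject(obj)
  obj
}

## Per-group moments from pooled marginals plus standardized effects:
## with prevalence pi, pooled mean m and pooled SD s,
##   withinSD = s / sqrt(1 + pi (1 - pi) delta^2)
##   meanNeg  = m - pi * delta * withinSD,  meanPos = meanNeg + delta * withinSD
## which reproduces the pooled mean exactly (and the pooled SD exactly
## for equal within-group SDs).  For the right-skewed log-scale
## biomarkers the within-group SDs are made coefficient-of-variation
## preserving (sd_g proportional to mean_g): disease shifts skewed
## counts multiplicatively, and a shared absolute SD would give the
## low-mean group an implausibly extreme CV.  The pooled SD anchor is
## then approximate (within a few percent) while pooled means stay
## exact.
.specFromEffects <- function(nPos, nNeg, effects, corr,
                             culturePosFraction, seed,
                             marginals = .defaultMarginals()) {
  nm <- rownames(marginals)
  delta <- stats::setNames(numeric(length(nm)), nm)
  delta[names(effects)] <- effects
  pi <- nPos / (nPos + nNeg)
  sw <- marginals$sd / sqrt(1 + pi * (1 - pi) * delta^2)
  Delta <- delta * sw
  meanNeg <- stats::setNames(marginals$mean - pi * Delta, nm)
  meanPos <- stats::setNames(meanNeg + Delta, nm)
  isLog <- nm %in% LOG_SCALE_BIOMARKERS
  sdNeg <- sdPos <- stats::setNames(sw, nm)
  sdNeg[isLog] <- sw[isLog] * meanNeg[isLog] / marginals$mean[isLog]
  sdPos[isLog] <- sw[isLog] * meanPos[isLog] / marginals$mean[isLog]
  cohortSpec(nPos, nNeg,
             meanPos = meanPos, meanNeg = meanNeg,
             sdPos = sdPos, sdNeg = sdNeg,
             corr = corr,
             informative = which(delta != 0),
             culturePosFraction = culturePosFraction, seed = seed)
}

#' Default synthetic NICU cohort specification
#'
#' Pooled marginals anchor the five panel biomarkers to the published
#' cohort values (WBC 14.04/8.70, Plt 231.37/103.38, Segs 39.64/17.25,
#' Bands 7.92/9.61, CD64 2.96/2.42); the informative-set effects follow
#' the classifier's sign pattern; the correlation target is
#' [defaultCorrelation()].
#'
#' @param nPos,nNeg Group sizes (default 200 septic / 400 nonseptic).
#' @param effectSizes Named standardized group-mean differences.
#' @param culturePosFraction,seed See [cohortSpec()].
#' @return A [CohortSpec].
#' @export
defaultCohortSpec <- function(nPos = 200, nNeg = 400,
                              effectSizes = .defaultEffects(),
                              culturePosFraction = 0.5, seed = 1L) {
  .specFromEffects(nPos, nNeg, effectSizes, defaultCorrelation(),
                   culturePosFraction, seed)
}

## ---------------------------------------------------------------------
## Nataf-style latent correlation adjustment
## ---------------------------------------------------------------------

## The generator draws a latent Gaussian vector and transforms each
## margin (identity or lognormal).  To make the *output* Pearson
## correlations match the spec target, each pairwise latent correlation
## is back-solved from the target:
##   log-log:  rz = log(1 + rx sqrt((e^{si^2}-1)(e^{sj^2}-1))) / (si sj)
##   log-raw:  rz = rx sqrt(e^{s^2}-1) / s
##   raw-raw:  rz = rx
.latentCorrelation <- function(corr, logSd, isLog) {
  p <- nrow(corr)
  Rz <- corr
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    rx <- corr[i, j]
    if (rx == 0) { Rz[i, j] <- Rz[j, i] <- 0; next }
    if (isLog[i] && isLog[j]) {
      a <- sqrt(expm1(logSd[i]^2) * expm1(logSd[j]^2))
      arg <- 1 + rx * a
      if (arg <= 0)
        stop("target correlation ", rx, " infeasible for lognormal pair ",
             i, ",", j)
      rz <- log(arg) / (logSd[i] * logSd[j])
    } else if (isLog[i] || isLog[j]) {
      s <- if (isLog[i]) logSd[i] else logSd[j]
      rz <- rx * sqrt(expm1(s^2)) / s
    } else rz <- rx
    Rz[i, j] <- Rz[j, i] <- min(0.999, max(-0.999, rz))
  }
  ev <- min(eigen(Rz, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-8) {
    warning("latent correlation matrix adjusted to nearest positive definite")
    Rz <- as.matrix(Matrix::nearPD(Rz, corr = TRUE)$mat)
  }
  Rz
}

## Draw one group's biomarker matrix (n x p, raw units).
.drawGroup <- function(n, m, s, corr, isLog) {
  p <- length(m)
  if (any(isLog & m <= 0))
    stop("log-scale biomarkers need positive means")
  logSd <- numeric(p)
  logMu <- numeric(p)
  logSd[isLog] <- sqrt(log1p((s[isLog] / m[isLog])^2))
  logMu[isLog] <- log(m[isLog]) - logSd[isLog]^2 / 2
  Rz <- .latentCorrelation(corr, logSd, isLog)
  Z <- matrix(rnorm(n * p), n, p) %*% chol(Rz)
  X <- matrix(0, n, p)
  X[, isLog] <- exp(sweep(sweep(Z[, isLog, drop = FALSE], 2,
                                logSd[isLog], "*"),
                          2, logMu[isLog], "+"))
  X[, !isLog] <- pmax(0, sweep(sweep(Z[, !isLog, drop = FALSE], 2,
                                     s[!isLog], "*"),
                               2, m[!isLog], "+"))
  colnames(X) <- names(m)
  X
}

## ---------------------------------------------------------------------
## generateCohort
## ---------------------------------------------------------------------

#' Generate a synthetic sepsis-evaluation cohort
#'
#' Draws `nPos` septic and `nNeg` nonseptic evaluations with the
#' marginal moments and Pearson correlation structure of the
#' specification (lognormal margins for the right-skewed biomarkers,
#' truncated Gaussian otherwise).  The score-rule inputs are derived
#' from the standard CBC relationships (`ANC = WBC x Segs%%`,
#' `ABC = WBC x Bands%%`, `IT = ABC / (ABC + ANC)`, counts in
#' cells/mm^3), and blood-culture status is drawn for the septic group
#' at `culturePosFraction`.
#'
#' By definition, clinical-sepsis (group 2) evaluations have a positive
#' hematologic score and nonseptic (group 3) evaluations a negative
#' one.  With `ensureScoreConsistency = TRUE` (default) the generator
#' enforces this: septic draws whose derived score is negative are
#' recorded as culture-positive (group 1), and nonseptic draws whose
#' derived score is positive have their stored score inputs nudged just
#' inside the thresholds (biomarker values are never modified, so the
#' marginal structure is untouched).  Both adjustment counts are kept
#' in `metadata()`.
#'
#' @param spec A [CohortSpec].
#' @param thresholds [CriteriaThresholds] used for the consistency
#'   pass.
#' @param ensureScoreConsistency Enforce group/score consistency
#'   (default `TRUE`).
#' @return A [SepsisCohort] with `trueGroup` in `colData`.
#' @examples
#' coh <- generateCohort(defaultCohortSpec(nPos = 50, nNeg = 100))
#' table(sepsisGroups(makeLabels(coh)))
#' @export
generateCohort <- function(spec, thresholds = criteriaThresholds(),
                           ensureScoreConsistency = TRUE) {
  methods::validObject(spec)
  p <- length(spec@biomarkerNames)
  if (spec@nPos < p || spec@nNeg < p)
    warning("group size smaller than the number of biomarkers; ",
            "sample moments will be unstable")
  withSeed(spec@seed, {
    Xp <- .drawGroup(spec@nPos, spec@meanPos, spec@sdPos,
                     spec@corr, spec@logScale)
    Xn <- .drawGroup(spec@nNeg, spec@meanNeg, spec@sdNeg,
                     spec@corr, spec@logScale)
    X <- rbind(Xp, Xn)
    n <- nrow(X)
    septic <- c(rep(TRUE, spec@nPos), rep(FALSE, spec@nNeg))
    culture <- logical(n)
    culture[septic] <- runif(spec@nPos) < spec@culturePosFraction

    ## derived score-rule inputs (cells/mm^3; WBC is x10^3/uL)
    anc <- X[, "WBC"] * X[, "Segs"] * 10
    abc <- X[, "WBC"] * X[, "Bands"] * 10
    itRatio <- ifelse(abc + anc > 0, abc / (abc + anc), 0)
    plt <- X[, "Plt"]

    nForcedCulture <- 0L; nAdjustedScore <- 0L
    if (ensureScoreConsistency) {
      met <- .criteriaMet(anc, abc, itRatio, plt, thresholds)
      pos <- met >= 2L
      ## septic, culture-negative, score-negative -> record as culture+
      fix1 <- septic & !culture & !pos
      culture[fix1] <- TRUE
      nForcedCulture <- sum(fix1)
      ## nonseptic, score-positive -> nudge stored inputs inside
      fix2 <- which(!septic & pos)
      nAdjustedScore <- length(fix2)
      for (i in fix2) {
        if (itRatio[i] >= thresholds@itRatioMin)
          itRatio[i] <- 0.99 * thresholds@itRatioMin
        if (abc[i] >= thresholds@abcMin)
          abc[i] <- 0.99 * thresholds@abcMin
        m <- .criteriaMet(anc[i], abc[i], itRatio[i], plt[i], thresholds)
        if (m >= 2L && plt[i] <= thresholds@pltMax)
          plt[i] <- 1.01 * thresholds@pltMax
        m <- .criteriaMet(anc[i], abc[i], itRatio[i], plt[i], thresholds)
        if (m >= 2L)
          anc[i] <- min(max(anc[i], 1.01 * thresholds@ancLow),
                        0.99 * thresholds@ancHigh)
      }
    }

    trueGroup <- ifelse(septic, ifelse(culture, 1L, 2L), 3L)
    ids <- sprintf("ev%04d", seq_len(n))
    cd <- S4Vectors::DataFrame(
      dayOfLife = X[, "Age"],
      anc = anc, abc = abc, itRatio = itRatio, plt = plt,
      culturePositive = culture, trueGroup = as.integer(trueGroup),
      row.names = ids)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(biomarkers = t(X)),
      colData = cd)
    colnames(se) <- ids
    out <- methods::new("SepsisCohort", se)
    S4Vectors::metadata(out) <- list(
      spec = spec,
      nForcedCulture = nForcedCulture,
      nAdjustedScore = nAdjustedScore)
    out
  })
}

## ---------------------------------------------------------------------
## plantedPanelCohort
## ---------------------------------------------------------------------

#' Cohort with a planted informative biomarker panel
#'
#' A parameter-recovery harness: the named biomarkers receive the given
#' standardized group-mean differences; they are mutually uncorrelated
#' and uncorrelated with the uninformative biomarkers, so the planted
#' panel is the population-optimal subset of its size *by an
#' identifiable margin* (every member contributes its full effect).
#' Correlations among the uninformative biomarkers keep their default
#' values.  The realistic correlation structure, with its redundancy
#' and suppressor effects, belongs to [defaultCohortSpec()]; this
#' harness deliberately trades realism for an unambiguous ground
#' truth.
#'
#' @param informative Biomarker names or indices (may be empty for a
#'   null cohort).
#' @param effectSize Standardized mean differences, recycled along
#'   `informative`; sign gives direction (septic minus nonseptic).
#' @param nPos,nNeg Group sizes.
#' @param seed Integer RNG seed.
#' @param culturePosFraction See [cohortSpec()].
#' @return List with `cohort` (a [SepsisCohort]) and `groundTruth`
#'   (list: `informative` indices, named `effects`).
#' @examples
#' pp <- plantedPanelCohort("Bands", 2.0, nPos = 300, nNeg = 300)
#' pp$groundTruth$effects
#' @export
plantedPanelCohort <- function(informative, effectSize,
                               nPos = 300, nNeg = 300, seed = 1L,
                               culturePosFraction = 0.5) {
  nm <- BIOMARKERS
  if (is.character(informative)) {
    stopifnot2(all(informative %in% nm), "unknown biomarker name")
    idx <- match(informative, nm)
  } else idx <- as.integer(informative)
  stopifnot2(all(idx >= 1 & idx <= length(nm)),
             "informative indices out of range")
  stopifnot2(all(is.finite(effectSize)) || length(idx) == 0,
             "effect sizes must be finite")
  effects <- stats::setNames(rep_len(effectSize, length(idx)), nm[idx])
  corr <- defaultCorrelation()
  noise <- setdiff(seq_along(nm), idx)
  corr[idx, ] <- 0
  corr[, idx] <- 0
  diag(corr) <- 1
  spec <- .specFromEffects(nPos, nNeg, effects, corr,
                           culturePosFraction, seed)
  list(cohort = generateCohort(spec),
       groundTruth = list(informative = sort(idx), effects = effects))
}

## ---------------------------------------------------------------------
## Accessors
## ---------------------------------------------------------------------

#' @rdname biomarkerMatrix
#' @export
setMethod("biomarkerMatrix", "SepsisCohort", function(x)
  t(SummarizedExperiment::assay(x, "biomarkers")))

#' @rdname cultureStatus
#' @export
setMethod("cultureStatus", "SepsisCohort", function(x)
  SummarizedExperiment::colData(x)$culturePositive)

#' @rdname sepsisGroups
#' @export
setMethod("sepsisGroups", "SepsisCohort", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("group" %in% colnames(cd)) cd$group else cd$trueGroup
})

#' @rdname sepsisLabels
#' @export
setMethod("sepsisLabels", "SepsisCohort", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"label" %in% colnames(cd))
    stop("cohort has no labels yet; run makeLabels() first")
  cd$label
})

setMethod("show", "SepsisCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("SepsisCohort with", ncol(object), "evaluations and",
      nrow(object), "biomarkers\n")
  if ("group" %in% colnames(cd)) {
    tab <- table(factor(cd$group, levels = 1:3))
    cat(sprintf("  groups: %d culture-proven, %d clinical, %d nonseptic\n",
                tab[1], tab[2], tab[3]))
  } else if ("trueGroup" %in% colnames(cd)) {
    tab <- table(factor(cd$trueGroup, levels = 1:3))
    cat(sprintf("  trueGroup: %d culture-proven, %d clinical, %d nonseptic\n",
                tab[1], tab[2], tab[3]))
  }
  cat("  biomarkers:", paste(rownames(object), collapse = ", "), "\n")
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d septic + %d nonseptic, %d biomarkers, seed %d\n",
              object@nPos, object@nNeg,
              length(object@biomarkerNames), object@seed))
  inf <- object@biomarkerNames[object@informative]
  cat("  informative:",
      if (length(inf)) paste(inf, collapse = ", ") else "(none)", "\n")
})
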