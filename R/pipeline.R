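#' @include AllClasses.R
NULL

.cohortCsvColumns <- function()
  c("evalId", "dayOfLife", BIOMARKERS, "anc", "abc", "itRatio", "plt",
    "culturePositive", "trueGroup", "group", "label")

#' Write a cohort to CSV (with a JSON provenance sidecar)
#'
#' The CSV has a fixed documented header: `evalId`, `dayOfLife`, the
#' ten biomarkers, the score-rule inputs, `culturePositive`, and any
#' of `trueGroup`/`group`/`label` present in the cohort.  When the
#' cohort carries a generator specification, a `<path>.spec.json`
#' sidecar records it together with the seed.
#'
#' @param cohort A [SepsisCohort].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeCohortCsv <- function(cohort, path) {
  X <- biomarkerMatrix(cohort)
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  df <- data.frame(evalId = colnames(cohort), dayOfLife = cd$dayOfLife,
                   X, cd[, intersect(c("anc", "abc", "itRatio", "plt",
                                       "culturePositive", "trueGroup",
                                       "group", "label"),
                                     colnames(cd))],
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  spec <- S4Vectors::metadata(cohort)$spec
  if (!is.null(spec)) {
    side <- list(
      nPos = spec@nPos, nNeg = spec@nNeg, seed = spec@seed,
      biomarkerNames = spec@biomarkerNames,
      meanPos = spec@meanPos, meanNeg = spec@meanNeg,
      sdPos = spec@sdPos, sdNeg = spec@sdNeg,
      informative = spec@informative,
      culturePosFraction = spec@culturePosFraction,
      corr = spec@corr)
    jsonlite::write_json(side, paste0(path, ".spec.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Requires the ten biomarker columns and `culturePositive`; the
#' score-rule inputs are taken from the file when present and derived
#' from WBC/Segs/Bands otherwise.  Rows with unparseable numeric
#' fields are excluded with machine-readable reasons
#' (`"parse:<column>"`); unknown extra columns are ignored with a
#' warning.
#'
#' @param path CSV path.
#' @return List with `cohort` (a [SepsisCohort]) and `excluded`
#'   (data.frame `evalId`, `reason`).
#' @export
readCohortCsv <- function(path) {
  stopifnot2(file.exists(path), paste("no such file:", path))
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  needed <- c(BIOMARKERS, "culturePositive")
  miss <- setdiff(needed, colnames(raw))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(colnames(raw), .cohortCsvColumns())
  if (length(extra))
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  ids <- if ("evalId" %in% colnames(raw)) raw$evalId
         else sprintf("row%04d", seq_len(nrow(raw)))
  numCols <- intersect(c("dayOfLife", BIOMARKERS,
                         "anc", "abc", "itRatio", "plt"), colnames(raw))
  reason <- rep(NA_character_, nrow(raw))
  num <- list()
  for (j in numCols) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- is.na(reason) & is.na(v) &
      !is.na(raw[[j]]) & nzchar(trimws(raw[[j]])) &
      !toupper(trimws(raw[[j]])) %in% c("NA", "NAN")
    reason[bad] <- paste0("parse:", j)
    num[[j]] <- v
  }
  cult <- toupper(trimws(raw$culturePositive))
  cultVal <- ifelse(cult %in% c("TRUE", "T", "1", "YES"), TRUE,
                    ifelse(cult %in% c("FALSE", "F", "0", "NO"), FALSE, NA))
  bad <- is.na(reason) & is.na(cultVal) & nzchar(cult) &
    !cult %in% c("NA")
  reason[bad] <- "parse:culturePositive"
  keep <- is.na(reason)

  X <- do.call(cbind, num[BIOMARKERS])[keep, , drop = FALSE]
  colnames(X) <- BIOMARKERS
  anc <- if ("anc" %in% names(num)) num$anc[keep]
         else X[, "WBC"] * X[, "Segs"] * 10
  abc <- if ("abc" %in% names(num)) num$abc[keep]
         else X[, "WBC"] * X[, "Bands"] * 10
  itr <- if ("itRatio" %in% names(num)) num$itRatio[keep]
         else ifelse(abc + anc > 0, abc / (abc + anc), 0)
  plt <- if ("plt" %in% names(num)) num$plt[keep] else X[, "Plt"]
  cd <- S4Vectors::DataFrame(
    dayOfLife = if ("dayOfLife" %in% names(num)) num$dayOfLife[keep]
                else X[, "Age"],
    anc = anc, abc = abc, itRatio = itr, plt = plt,
    culturePositive = cultVal[keep],
    row.names = make.unique(ids[keep]))
  if ("trueGroup" %in% colnames(raw))
    cd$trueGroup <- as.integer(raw$trueGroup)[keep]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(biomarkers = t(X)), colData = cd)
  colnames(se) <- rownames(cd)
  list(cohort = methods::new("SepsisCohort", se),
       excluded = data.frame(evalId = ids[!keep],
                             reason = reason[!keep],
                             stringsAsFactors = FALSE))
}

## ---------------------------------------------------------------------
## End-to-end pipeline
## ---------------------------------------------------------------------

#' Pipeline run configuration
#'
#' A single configuration object drives [runPipeline()]; there are no
#' hidden defaults outside it, and its hash is written into every
#' emitted table so outputs are traceable to their configuration.
#'
#' @param spec A [CohortSpec] (synthetic input), or `NULL` when
#'   `csvPath` is given.
#' @param csvPath Path to a cohort CSV, or `NULL`.
#' @param thresholds [CriteriaThresholds] for labeling.
#' @param kRange Subset sizes for selection and per-k evaluation.
#' @param kReport Panel size for the detailed model report and ROC.
#' @param R,B,scale Evaluation divisions, ensemble size, cost scale.
#' @param lambda LLR penalty (`NULL` = cross-validated).
#' @param seed Master seed.
#' @param outDir Output directory (created if needed).
#' @param standardizeOn `"all"` (default) or `"learning"`.
#' @param cd64Cutoff Optional CD64 outlier cutoff.
#' @param doValidation Run the exhaustive all-subsets sweep.
#' @param validationR,validationB Reduced settings for the sweep.
#' @return A `sepsisRunConfig` list.
#' @export
runConfig <- function(spec = defaultCohortSpec(), csvPath = NULL,
                      thresholds = criteriaThresholds(),
                      kRange = 1:10, kReport = 5, R = 20, B = 50,
                      scale = 1, lambda = NULL, seed = 1L,
                      outDir = tempfile("sepsisPanel-run-"),
                      standardizeOn = "all", cd64Cutoff = NULL,
                      doValidation = TRUE,
                      validationR = 3, validationB = 5) {
  if (!is.null(csvPath))
    stopifnot2(file.exists(csvPath), paste("no such file:", csvPath))
  cfg <- list(spec = spec, csvPath = csvPath, thresholds = thresholds,
              kRange = kRange, kReport = kReport, R = R, B = B,
              scale = scale, lambda = lambda, seed = as.integer(seed),
              outDir = outDir, standardizeOn = standardizeOn,
              cd64Cutoff = cd64Cutoff, doValidation = doValidation,
              validationR = validationR, validationB = validationB)
  class(cfg) <- "sepsisRunConfig"
  cfg
}

.configHash <- function(cfg) {
  cfg$outDir <- NULL # hash is location-independent
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(utils::capture.output(utils::str(cfg, digits.d = 12)),
                   collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}

.thresholdHeader <- function(th, hash) {
  c(sprintf("# config: %s", hash),
    sprintf("# thresholds: ancLow=%g ancHigh=%g abcMin=%g itRatioMin=%g pltMax=%g (implementer-chosen defaults)",
            th@ancLow, th@ancHigh, th@abcMin, th@itRatioMin, th@pltMax))
}

.writeTable <- function(df, path, header, sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Run the full biomarker-panel analysis
#'
#' Sequences the end-to-end analysis: cohort input (synthetic or CSV),
#' exclusion of incomplete records, labeling, exhaustive
#' canonical-correlation subset selection, bagged-SSVM and LLR
#' evaluation per subset size, the detailed model report at
#' `kReport`, averaged ROC curves, and (optionally) the exhaustive
#' all-subsets validation sweep.  All artifacts are written under
#' `config$outDir` together with a manifest carrying the seed and
#' configuration hash; identical configurations give byte-identical
#' outputs.
#'
#' @param config A [runConfig()] object.
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the in-memory results
#'   (`cohort`, `path`, `performance`, `model`, `roc`, `sweep`,
#'   `pvalues`, `outDir`).
#' @export
runPipeline <- function(config = runConfig(), quiet = FALSE) {
  stopifnot2(inherits(config, "sepsisRunConfig"),
             "config must come from runConfig()")
  hash <- .configHash(config)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[sepsisPanel] ", ...)
  stage <- "input"
  res <- tryCatch({
    ## ----- input -----
    cohort <- if (!is.null(config$csvPath)) {
      rd <- readCohortCsv(config$csvPath)
      if (nrow(rd$excluded))
        say(nrow(rd$excluded), " rows failed to parse")
      rd$cohort
    } else generateCohort(config$spec, thresholds = config$thresholds)
    say("input: ", ncol(cohort), " evaluations")

    stage <- "exclusion"
    ex <- excludeIncomplete(cohort, cd64Cutoff = config$cd64Cutoff)
    cohort <- ex$kept
    .writeTable(ex$excluded, file.path(config$outDir, "exclusions.tsv"),
                .thresholdHeader(config$thresholds, hash))
    say("exclusion: ", ncol(cohort), " kept, ",
        nrow(ex$excluded), " excluded")

    stage <- "labeling"
    cohort <- makeLabels(cohort, config$thresholds)
    y <- sepsisLabels(cohort)
    X <- biomarkerMatrix(cohort)
    say("labeling: ", sum(y > 0), " septic / ", sum(y < 0), " nonseptic")

    stage <- "screening"
    pv <- univariatePvalues(X, y)
    .writeTable(pv, file.path(config$outDir, "univariate_pvalues.tsv"),
                .thresholdHeader(config$thresholds, hash))

    stage <- "selection"
    path <- bestSubsets(X, y, config$kRange)
    tb <- selectionTable(path)
    fs <- selectionTable(path, "fs")
    selTab <- data.frame(k = tb$k, correlation = round(tb$rho, 3),
                         enter = tb$enter, leave = tb$leave,
                         forward_selection = fs[seq_len(nrow(tb))])
    .writeTable(selTab, file.path(config$outDir, "selection_path.tsv"),
                .thresholdHeader(config$thresholds, hash))
    say("selection: best panel at k = ", config$kReport, ": ",
        paste(path@biomarkerNames[selectedSubset(path, config$kReport)],
              collapse = ", "))

    stage <- "training"
    seeds <- childSeeds(config$seed, 4L)
    divisions <- makeDivisions(y, config$R, seed = seeds[1])
    perK <- lapply(config$kRange, function(k) {
      feats <- path@biomarkerNames[selectedSubset(path, k)]
      list(k = k,
           ssvm = repeatedEvaluation(X, y, feats, R = config$R,
                                     B = config$B, seed = seeds[2],
                                     scale = config$scale,
                                     divisions = divisions,
                                     standardizeOn = config$standardizeOn,
                                     keepScores = TRUE),
           llr = repeatedEvaluation(X, y, feats, R = config$R,
                                    seed = seeds[3], method = "LLR",
                                    divisions = divisions,
                                    standardizeOn = config$standardizeOn,
                                    lambda = config$lambda))
    })
    perfRows <- do.call(rbind, lapply(perK, function(e)
      rbind(cbind(k = e$k, performanceTable(e$ssvm)),
            cbind(k = e$k, performanceTable(e$llr)))))
    .writeTable(perfRows, file.path(config$outDir, "performance.tsv"),
                .thresholdHeader(config$thresholds, hash))

    iRep <- match(config$kReport, config$kRange)
    rep5 <- perK[[iRep]]$ssvm
    sm <- standardizeBiomarkers(X[, rep5@features, drop = FALSE])
    model <- list(biomarkers = rep5@features,
                  weight = rep5@weightMean,
                  weightSE = rep5@weightSE,
                  mean = sm@mu, sd = sm@sigma,
                  B = config$B, R = config$R, seed = config$seed,
                  scale = config$scale, configHash = hash)
    jsonlite::write_json(model,
                         file.path(config$outDir,
                                   sprintf("model_k%d.json", config$kReport)),
                         auto_unbox = TRUE, digits = NA)

    stage <- "roc"
    roc <- averageRoc(rep5@rocs)
    .writeTable(rocTable(roc),
                file.path(config$outDir,
                          sprintf("roc_k%d.csv", config$kReport)),
                .thresholdHeader(config$thresholds, hash), sep = ",")
    say("roc: mean AUC ", round(roc@aucMean, 3))

    stage <- "validation"
    sweep <- NULL
    if (isTRUE(config$doValidation)) {
      sweep <- exhaustiveValidation(X, y, kRange = config$kRange,
                                    R = config$validationR,
                                    B = config$validationB,
                                    seed = seeds[4],
                                    scale = config$scale, path = path)
      jsonlite::write_json(
        list(configHash = hash, kRange = sweep@kRange,
             R = sweep@R, B = sweep@B,
             ccaRanks = as.data.frame(sweep@ccaRanks),
             results = sweep@results),
        file.path(config$outDir, "validation_sweep.json"),
        auto_unbox = TRUE, digits = NA)
      say("validation: CCA panel ACC rank at k = ", config$kReport,
          ": ", sweep@ccaRanks[paste0("k", config$kReport), "ACC"])
    }

    stage <- "manifest"
    manifest <- list(configHash = hash, seed = config$seed,
                     n = ncol(cohort), nSeptic = sum(y > 0),
                     nNonseptic = sum(y < 0),
                     kRange = config$kRange, R = config$R, B = config$B,
                     scale = config$scale,
                     standardizeOn = config$standardizeOn,
                     artifacts = sort(list.files(config$outDir)))
    jsonlite::write_json(manifest,
                         file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)

    list(cohort = cohort, path = path, performance = perK,
         model = model, roc = roc, sweep = sweep, pvalues = pv,
         outDir = config$outDir)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}
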