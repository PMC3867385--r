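#' @include utils.R
NULL

#' Biomarker matrix of a cohort
#'
#' Returns the biomarker values of a [SepsisCohort] as an evaluations
#' x biomarkers numeric matrix (the orientation used by the selection
#' and classification functions).
#'
#' @param x A `SepsisCohort`.
#' @return A numeric matrix with one row per evaluation.
#' @export
setGeneric("biomarkerMatrix", function(x) standardGeneric("biomarkerMatrix"))

#' Blood-culture status of each evaluation
#' @param x A `SepsisCohort`.
#' @return Logical vector, `TRUE` for culture-positive evaluations.
#' @export
setGeneric("cultureStatus", function(x) standardGeneric("cultureStatus"))

#' Three-group sepsis outcome of each evaluation
#'
#' Group 1 = culture-proven sepsis, group 2 = clinical sepsis (positive
#' hematologic score without a positive culture), group 3 = nonseptic.
#'
#' @param x A `SepsisCohort`.
#' @return Integer vector in `{1, 2, 3}` (or `NA` before labeling).
#' @export
setGeneric("sepsisGroups", function(x) standardGeneric("sepsisGroups"))

#' Septic/nonseptic class labels
#' @param x A `SepsisCohort`.
#' @return Numeric vector in `{+1, -1}`: `+1` for groups 1 and 2.
#' @export
setGeneric("sepsisLabels", function(x) standardGeneric("sepsisLabels"))

#' Linear decision values on new data
#'
#' Applies the stored standardization and evaluates the linear score
#' `w . x + b` for each row of `newdata` (raw biomarker units).
#'
#' @param object A [LinearDecisionFunction] or [SSVMEnsemble].
#' @param newdata Numeric matrix (evaluations x biomarkers) whose columns
#'   match `panelNames(object)`.
#' @return Numeric vector of decision values (ensembles: member mean).
#' @export
setGeneric("decisionValues",
           function(object, newdata) standardGeneric("decisionValues"))

#' Biomarker weights of a fitted classifier
#' @param object A [LinearDecisionFunction] or [SSVMEnsemble].
#' @return Named numeric vector of weights on the standardized scale
#'   (ensembles: mean over members).
#' @export
setGeneric("panelWeights", function(object) standardGeneric("panelWeights"))

#' Biomarker names a model was fitted on
#' @param object A fitted model object.
#' @return Character vector.
#' @export
setGeneric("panelNames", function(object) standardGeneric("panelNames"))
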