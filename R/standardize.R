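#' @include AllClasses.R
NULL

#' Standardize a biomarker matrix to zero mean and unit SD
#'
#' Each column is centred by its mean and divided by its sample SD
#' (n-1 denominator), giving the dimensionless matrix the selection and
#' classification steps operate on.  The fitted `mu`/`sigma` are stored
#' so the identical affine map can be applied to new samples in raw
#' measurement units.
#'
#' @param X Numeric matrix, evaluations x biomarkers (n >= 2, no
#'   missing values).
#' @param fittedOn Provenance tag, `"all"` (default; parameters fitted
#'   on the complete dataset) or `"learning"`.
#' @return A [StandardizedMatrix].
#' @examples
#' sm <- standardizeBiomarkers(matrix(rnorm(40), 10, 4))
#' colMeans(standardizedValues(sm))   # ~0
#' @export
standardizeBiomarkers <- function(X, fittedOn = c("all", "learning")) {
  fittedOn <- match.arg(fittedOn)
  X <- as.matrix(X)
  stopifnot2(nrow(X) >= 2, "standardization needs at least 2 rows")
  stopifnot2(!anyNA(X), "X must not contain missing values")
  mu <- colMeans(X)
  sigma <- apply(X, 2, sd)
  zero <- sigma <= 0 | !is.finite(sigma)
  if (any(zero)) {
    nm <- colnames(X) %||% as.character(seq_len(ncol(X)))
    stop("zero-variance biomarker(s): ", paste(nm[zero], collapse = ", "))
  }
  names(mu) <- names(sigma) <- colnames(X)
  new("StandardizedMatrix",
      values = sweep(sweep(X, 2, mu, "-"), 2, sigma, "/"),
      mu = mu, sigma = sigma, fittedOn = fittedOn)
}

#' Apply a frozen standardization to new samples
#'
#' @param X Numeric matrix (or vector treated as one row) in raw units;
#'   column count must match `length(mu)`.
#' @param mu,sigma Standardization parameters from a previous fit.
#' @return Standardized numeric matrix.
#' @export
applyStandardization <- function(X, mu, sigma) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != length(mu))
    stop("dimension mismatch: ", ncol(X), " columns vs ",
         length(mu), " standardization parameters")
  sweep(sweep(X, 2, mu, "-"), 2, sigma, "/")
}

#' Standardized values of a StandardizedMatrix
#' @param x A [StandardizedMatrix].
#' @return The n x p standardized matrix.
#' @export
standardizedValues <- function(x) x@values

#' Standardization parameters
#' @param x A [StandardizedMatrix].
#' @return Named list with `mu` and `sigma`.
#' @export
standardizationParams <- function(x) list(mu = x@mu, sigma = x@sigma)
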