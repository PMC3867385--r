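#' @include AllClasses.R
NULL

#' LASSO logistic regression comparator
#'
#' Fits the l1-penalized logistic model
#' `min sum_i log(1 + exp(-y_i (w . x_i + b))) + lambda * sum_j |w_j|`
#' (bias unpenalized), the standard sparse comparator to the 1-norm
#' SVM.  The optimization is delegated to glmnet's coordinate descent
#' (penalty rescaled to glmnet's per-observation parameterization); the
#' solution satisfies the objective to glmnet's convergence threshold
#' (`thresh = 1e-12`).
#'
#' @param X Feature matrix (conventionally standardized).
#' @param y Labels in `{+1, -1}`.
#' @param lambda Penalty on the summed-loss scale above; `0` gives the
#'   unpenalized MLE.  `NULL` (default) selects lambda by `nfolds`-fold
#'   cross-validated binomial deviance over a 30-point log grid.
#' @param nfolds CV folds when `lambda` is `NULL`.
#' @param seed Seed for the CV fold assignment.
#' @param mu,sigma Optional standardization parameters stamped into
#'   the returned model.
#' @return A [LinearDecisionFunction].
#' @export
fitLLR <- function(X, y, lambda = NULL, nfolds = 5, seed = 1L,
                   mu = NULL, sigma = NULL) {
  X <- as.matrix(X)
  stopifnot2(all(y %in% c(-1, 1)), "labels must be +1/-1")
  stopifnot2(is.null(lambda) || lambda >= 0, "lambda must be >= 0")
  n <- nrow(X)
  k <- ncol(X)
  nm <- colnames(X) %||% paste0("V", seq_len(k))
  yy <- factor(y, levels = c(-1, 1))
  ## glmnet requires >= 2 columns; pad single-biomarker panels with a
  ## zero column (its coefficient is identically zero) and strip after
  pad <- k == 1L
  if (pad) X <- cbind(X, 0)
  if (is.null(lambda)) {
    cv <- withSeed(seed, glmnet::cv.glmnet(
      X, yy, family = "binomial", nfolds = nfolds,
      nlambda = 30, type.measure = "deviance",
      standardize = FALSE))
    lamG <- cv$lambda.min
    fit <- glmnet::glmnet(X, yy, family = "binomial",
                          lambda = cv$lambda, thresh = 1e-12,
                          maxit = 1e6, standardize = FALSE)
    co <- coef(fit, s = lamG)
  } else {
    lamG <- lambda / n
    ## descending path ending at the requested value stabilizes
    ## coordinate descent, including the unpenalized endpoint
    path <- sort(unique(c(lamG * c(100, 10, 3, 1),
                          if (lamG == 0) c(1, 0.1, 0.01))),
                 decreasing = TRUE)
    fit <- glmnet::glmnet(X, yy, family = "binomial", lambda = path,
                          thresh = 1e-12, maxit = 1e6,
                          standardize = FALSE)
    co <- coef(fit, s = lamG, exact = TRUE, x = X, y = yy)
  }
  w <- drop(co)[-1]
  b <- drop(co)[1]
  if (pad) w <- w[1]
  if (!all(is.finite(c(w, b))))
    stop("LLR fit did not converge; non-finite coefficients")
  new("LinearDecisionFunction",
      w = stats::setNames(w, nm), b = unname(b),
      mu = stats::setNames(mu %||% rep(0, k), nm),
      sigma = stats::setNames(sigma %||% rep(1, k), nm))
}
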