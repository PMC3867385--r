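#' @include AllClasses.R
NULL

## Canonical correlation against a univariate label reduces to the
## multiple correlation coefficient: the maximal Pearson correlation
## between y and any linear combination of the columns of X equals
## sqrt(R^2) of the least-squares regression of y on X (with
## intercept).  This is computed through a pseudo-inverse so
## rank-deficient subsets degrade gracefully instead of crashing.

#' Canonical correlation between a biomarker subset and the label
#'
#' @param X Numeric matrix (evaluations x selected biomarkers).
#' @param y Numeric label vector (conventionally +1/-1); must not be
#'   constant.
#' @return The canonical correlation in `[0, 1]`.
#' @examples
#' X <- matrix(rnorm(120), 40, 3); y <- sign(X[, 1] + rnorm(40))
#' canonicalCorrelation(X, y)
#' @export
canonicalCorrelation <- function(X, y) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  X <- as.matrix(X)
  stopifnot2(nrow(X) == length(y), "X and y lengths differ")
  stopifnot2(nrow(X) > ncol(X), "need more samples than biomarkers")
  yc <- y - mean(y)
  tss <- sum(yc^2)
  stopifnot2(tss > 0, "y is constant; canonical correlation undefined")
  Xc <- sweep(X, 2, colMeans(X), "-")
  beta <- pinvMat(Xc) %*% yc
  rss <- sum((yc - Xc %*% beta)^2)
  rho2 <- 1 - rss / tss
  sqrt(min(1, max(0, rho2)))
}

## rho^2 of subset S from precomputed correlation structure:
## R^2 = r_S' Rss^{-1} r_S (with pseudo-inverse fallback).
.subsetRho2 <- function(Cxx, cxy, S) {
  r <- cxy[S]
  RS <- Cxx[S, S, drop = FALSE]
  v <- tryCatch(drop(crossprod(r, solve(RS, r))),
                error = function(e) drop(crossprod(r, pinvMat(RS) %*% r)))
  min(1, max(0, v))
}

#' Exhaustive best biomarker subsets by canonical correlation
#'
#' For each subset size k, every one of the C(p, k) subsets is scored
#' by its canonical correlation with the label and the globally best
#' subset is retained (first-seen maximum under strict comparison, so
#' ties resolve to the lexicographically smallest index tuple).  The
#' `enter`/`leave` columns annotate the set differences between
#' consecutive winners, and the greedy Forward Selection order is
#' attached for comparison.
#'
#' @param X Numeric matrix, evaluations x biomarkers (p <= 25).
#' @param y Label vector (+1/-1).
#' @param kRange Subset sizes to search (default `1:p`).
#' @return A [SelectionPath].
#' @export
bestSubsets <- function(X, y, kRange = seq_len(ncol(X))) {
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot2(p <= 25,
             "exhaustive enumeration is limited to p <= 25 biomarkers; use forwardSelection() for larger panels")
  stopifnot2(all(kRange >= 1 & kRange <= p), "kRange must lie in 1..p")
  kRange <- sort(unique(as.integer(kRange)))
  nm <- colnames(X) %||% paste0("V", seq_len(p))
  Cxx <- cor(X)
  cxy <- drop(cor(X, y))
  rows <- vector("list", length(kRange))
  prev <- integer()
  for (i in seq_along(kRange)) {
    k <- kRange[i]
    combos <- combn(p, k)
    bestRho2 <- -1; bestS <- NULL
    for (q in seq_len(ncol(combos))) {
      S <- combos[, q]
      v <- .subsetRho2(Cxx, cxy, S)
      if (v > bestRho2) { bestRho2 <- v; bestS <- S }
    }
    enter <- setdiff(bestS, prev)
    leave <- setdiff(prev, bestS)
    rows[[i]] <- data.frame(
      k = k, rho = sqrt(bestRho2),
      subset = I(list(bestS)),
      enter = paste(nm[enter], collapse = ","),
      leave = paste(nm[leave], collapse = ","),
      stringsAsFactors = FALSE)
    prev <- bestS
  }
  new("SelectionPath",
      table = do.call(rbind, rows),
      fsOrder = forwardSelection(X, y),
      biomarkerNames = nm)
}

#' Greedy Forward Selection order
#'
#' At each step the residual of y on the selected biomarkers (with
#' intercept) is computed, and the unselected biomarker with the
#' highest absolute Pearson correlation with that residual enters.
#' Ties break lexicographically; if the residual becomes numerically
#' zero the remaining biomarkers are appended in index order with a
#' warning.
#'
#' @inheritParams bestSubsets
#' @return Character vector of biomarker names in selection order.
#' @export
forwardSelection <- function(X, y) {
  X <- as.matrix(X)
  p <- ncol(X)
  nm <- colnames(X) %||% paste0("V", seq_len(p))
  selected <- integer()
  remaining <- seq_len(p)
  resid <- y - mean(y)
  while (length(remaining)) {
    if (sd(resid) < 1e-12) {
      warning("residual is numerically zero; remaining biomarkers appended in index order")
      selected <- c(selected, remaining)
      break
    }
    cors <- abs(apply(X[, remaining, drop = FALSE], 2,
                      function(x) {
                        if (sd(x) == 0) return(0)
                        cor(x, resid)
                      }))
    pick <- remaining[which.max(cors)] # which.max: first max = lexicographic
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    fit <- stats::lm.fit(cbind(1, X[, selected, drop = FALSE]), y)
    resid <- fit$residuals
  }
  nm[selected]
}

#' Within-group pairwise biomarker correlations
#'
#' Pearson correlation matrices computed separately in the septic
#' (y = +1) and nonseptic (y = -1) groups, with biomarkers ordered by
#' the magnitude of their overall correlation with the label
#' (ascending), the ordering used for heatmap display.  A biomarker
#' constant within a group has its correlations reported as 0 and is
#' listed in the `flagged` element.
#'
#' @inheritParams bestSubsets
#' @return List with `septic`, `nonseptic` (p x p matrices), `order`
#'   (display order of biomarker names) and `flagged`.
#' @export
groupwiseCorrelations <- function(X, y) {
  X <- as.matrix(X)
  nm <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  colnames(X) <- nm
  stopifnot2(sum(y > 0) >= 3 && sum(y < 0) >= 3,
             "each group needs at least 3 evaluations")
  grpCor <- function(Xg) {
    sds <- apply(Xg, 2, sd)
    flag <- nm[sds == 0]
    M <- suppressWarnings(cor(Xg))
    M[!is.finite(M)] <- 0
    diag(M) <- 1
    list(M = M, flag = flag)
  }
  a <- grpCor(X[y > 0, , drop = FALSE])
  b <- grpCor(X[y < 0, , drop = FALSE])
  ord <- nm[order(abs(drop(cor(X, y))))]
  list(septic = a$M, nonseptic = b$M, order = ord,
       flagged = union(a$flag, b$flag))
}

setMethod("show", "SelectionPath", function(object) {
  cat("SelectionPath over", length(object@biomarkerNames),
      "biomarkers\n")
  tb <- object@table
  for (i in seq_len(nrow(tb)))
    cat(sprintf("  k=%2d rho=%.3f  enter: %-12s leave: %s\n",
                tb$k[i], tb$rho[i], tb$enter[i], tb$leave[i]))
  cat("  forward selection:", paste(object@fsOrder, collapse = ", "),
      "\n")
})

#' Selection-path table
#' @param path A [SelectionPath].
#' @param what `"table"` for the per-k data.frame, `"fs"` for the
#'   Forward Selection order.
#' @return The requested component.
#' @export
selectionTable <- function(path, what = c("table", "fs")) {
  what <- match.arg(what)
  if (what == "fs") path@fsOrder else path@table
}

#' Best subset of a given size from a selection path
#' @param path A [SelectionPath].
#' @param k Subset size.
#' @return Integer indices of the best k-subset.
#' @export
selectedSubset <- function(path, k) {
  i <- match(k, path@table$k)
  stopifnot2(!is.na(i), "k not present in the selection path")
  path@table$subset[[i]]
}
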