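#' @include AllClasses.R
NULL

## Linear-programming core of the 1-norm SVM.
##
## Primal:  min  sum_j |w_j| + sum_i c_i xi_i
##          s.t. y_i (w . x_i + b) >= 1 - xi_i,   xi >= 0,  b free
##
## written as an LP via w = u - v, b = bp - bm (all >= 0).  Its dual is
##
##          max  sum_i alpha_i
##          s.t. sum_i alpha_i y_i = 0
##               |sum_i alpha_i y_i x_ij| <= 1      (j = 1..k)
##               0 <= alpha_i <= c_i
##
## with only 2k+1 rows, which is what makes bootstrap-aggregated
## ensembles cheap: the simplex work scales with the number of features,
## not the number of samples.  The optimal primal (w, b) is read off the
## simplex multipliers of the dual (w_j = pi[j-] - pi[j+], b = -pi[0]),
## and xi is completed as the hinge max(0, 1 - y f), which leaves the
## objective unchanged at an optimum.

## Solve the dual LP.  Returns list(w, b, xi, objective, iterations).
ssvmSolveDual <- function(X, y, ci, tol = 1e-9) {
  n <- nrow(X); k <- ncol(X)
  Yx <- X * y
  ## rows: equality (y' alpha = 0), then j+ and j- bound rows
  A <- rbind(y, t(Yx), -t(Yx))
  ## columns: alpha (n), slacks (2k), a0 (fixed at 0, carries the
  ## equality row in the initial basis)
  A <- cbind(A, rbind(0, diag(2 * k)), c(1, rep(0, 2 * k)))
  bvec <- c(0, rep(1, 2 * k))
  cvec <- c(rep(-1, n), rep(0, 2 * k), 0)
  lb <- rep(0, n + 2 * k + 1)
  ub <- c(ci, rep(Inf, 2 * k), 0)
  basis0 <- as.integer(c(n + 2 * k + 1, n + seq_len(2 * k)))
  r <- cpp_bounded_simplex(A, bvec, cvec, lb, ub, basis0, tol = tol)
  if (r$status != 0)
    stop("SSVM dual LP did not converge (simplex status ", r$status, ")")
  piv <- r$pi
  b <- -piv[1]
  w <- piv[(k + 2):(2 * k + 1)] - piv[2:(k + 1)]
  f <- drop(X %*% w) + b
  xi <- pmax(0, 1 - y * f)
  list(w = w, b = b, xi = xi,
       objective = sum(abs(w)) + sum(ci * xi),
       dualObjective = -r$obj, iterations = r$iterations)
}

## Solve the primal LP directly (slower; cross-route and fallback).
ssvmSolvePrimal <- function(X, y, ci, tol = 1e-9) {
  n <- nrow(X); k <- ncol(X)
  Yx <- X * y
  ## equality form: -(Yx)(u - v) - y (bp - bm) - xi + s = -1
  A <- cbind(-Yx, Yx, -y, y, -diag(n), diag(n))
  bvec <- rep(-1, n)
  cvec <- c(rep(1, 2 * k), 0, 0, ci, rep(0, n))
  nv <- 2 * k + 2 + 2 * n
  lb <- rep(0, nv)
  ub <- rep(Inf, nv)
  basis0 <- as.integer(2 * k + 2 + seq_len(n)) # xi basis: values 1, feasible
  r <- cpp_bounded_simplex(A, bvec, cvec, lb, ub, basis0, tol = tol)
  if (r$status != 0)
    stop("SSVM primal LP did not converge (simplex status ", r$status, ")")
  x <- r$x
  w <- x[seq_len(k)] - x[k + seq_len(k)]
  b <- x[2 * k + 1] - x[2 * k + 2]
  xi <- x[2 * k + 2 + seq_len(n)]
  list(w = w, b = b, xi = xi, objective = r$obj,
       iterations = r$iterations)
}

## Entry point used by fitSSVM: dual route with a primal fallback if the
## duality gap check fails (degenerate multiplier recovery).
ssvmSolveLP <- function(X, y, ci, method = c("dual", "primal"),
                        tol = 1e-9) {
  method <- match.arg(method)
  if (method == "primal") return(ssvmSolvePrimal(X, y, ci, tol))
  r <- ssvmSolveDual(X, y, ci, tol)
  gap <- abs(r$objective - r$dualObjective) /
    max(1, abs(r$dualObjective))
  if (!is.finite(gap) || gap > 1e-7) {
    r <- ssvmSolvePrimal(X, y, ci, tol)
  }
  r
}
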