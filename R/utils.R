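#' @importFrom stats rnorm runif sd cor qnorm pnorm approx coef predict
#' @importFrom utils combn write.csv read.csv
NULL

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG
## stream.  All stochastic entry points funnel through this helper so that
## identical seeds give bit-identical results.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(
        rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Child seeds derived deterministically from a parent seed; kept below
## 2^31 so they remain valid R integers.
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

## Moore-Penrose pseudo-inverse via SVD (tolerance relative to the
## largest singular value, as in base qr-style rank decisions).
pinvMat <- function(M, tol = NULL) {
  s <- svd(M)
  if (is.null(tol)) tol <- max(dim(M)) * .Machine$double.eps * max(s$d, 0)
  pos <- s$d > tol
  if (!any(pos)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, pos, drop = FALSE] %*%
    ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot2 <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
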