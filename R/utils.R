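#' @importFrom methods new validObject is slot
#' @importFrom stats plogis qlogis rnorm runif rbinom var cov lm coef
#'   residuals model.matrix pt qt optimize uniroot setNames complete.cases
#'   aggregate p.adjust
#' @importFrom utils read.csv write.csv read.table write.table packageVersion
NULL

# Derive a reproducible child seed from a master seed and a stream tag so
# that each stochastic operation draws from its own named stream.
childSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647L)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

symmetrize <- function(m) (m + t(m)) / 2

# Eigenvalue flooring keeps covariance iterates positive semi-definite;
# the floor is relative to the matrix scale.
floorPSD <- function(m, rel = 1e-8) {
  m <- symmetrize(m)
  eg <- eigen(m, symmetric = TRUE)
  floorVal <- rel * max(sum(abs(diag(m))), .Machine$double.eps)
  if (all(eg$values >= floorVal)) return(m)
  vals <- pmax(eg$values, floorVal)
  out <- symmetrize(eg$vectors %*% (vals * t(eg$vectors)))
  dimnames(out) <- dimnames(m)
  out
}

isPSD <- function(m, tol = -1e-8) {
  if (!isSymmetric(unname(m), tol = 1e-6)) return(FALSE)
  min(eigen(symmetrize(m), symmetric = TRUE, only.values = TRUE)$values) >=
    tol * max(1, sum(abs(diag(m))))
}

# Decimal year of a Date, used for genetic-trend regressions.
decimalYear <- function(d) {
  d <- as.Date(d)
  yr <- as.integer(format(d, "%Y"))
  start <- as.Date(paste0(yr, "-01-01"))
  len <- as.numeric(as.Date(paste0(yr + 1L, "-01-01")) - start)
  yr + as.numeric(d - start) / len
}

`%||%` <- function(a, b) if (is.null(a)) b else a
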