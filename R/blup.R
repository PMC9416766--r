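## Multi-trait individual animal model BLUP: assembly of Henderson's
## mixed-model equations with per-record residual patterns (missing
## traits handled by inverting the observed submatrix of E), sparse
## solvers, exact prediction-error-variance reliabilities at desk scale,
## genetic-base rebasing, parity combination and realized genetic trends.

#' Assemble the mixed-model equations
#'
#' Builds Henderson's MME for the multi-trait animal model
#' y = Xb + Zu + e with u ~ N(0, A x G) and per-record residual
#' covariance taken as the observed submatrix of E (records may cover
#' any subset of traits). The genetic block is A-inverse kron G-inverse
#' over all pedigree animals; with `groups`, phantom-parent group
#' columns are appended (Westell/Quaas-Pollak), in which case a tiny
#' ridge stabilizes the otherwise singular group equations.
#'
#' @param phenotypes Long data.frame(animal, trait, value) with optional
#'   parity and hys columns; a record is one animal-parity combination.
#' @param ped A [Pedigree-class]; phenotyped animals must appear in it.
#' @param cov A [TraitCovariances-class]; variance components are
#'   assumed known.
#' @param fixed Fixed effects to fit: any of "hys" (per-trait class
#'   effects) and "parity" (per-trait shifts, first parity as base);
#'   defaults to those with columns present. `character(0)` fits no
#'   fixed effects.
#' @param groups Optional unknown-parent group map from
#'   [assignGroups()].
#' @param inbreeding Passed to [aInverse()].
#' @return List with the sparse symmetric coefficient matrix `C`, right
#'   hand side `rhs`, and index bookkeeping, for [solveMME()].
#' @export
buildMME <- function(phenotypes, ped, cov,
                     fixed = intersect(c("hys", "parity"),
                                       colnames(phenotypes)),
                     groups = NULL, inbreeding = NULL) {
  stopifnot(is(ped, "Pedigree"), is(cov, "TraitCovariances"))
  traits <- traitNames(cov)
  ph <- phenotypes[phenotypes$trait %in% traits, , drop = FALSE]
  if (nrow(ph) && !all(ph$animal %in% ped@id))
    stop("phenotype record references an animal missing from the pedigree")
  E <- envCov(cov); G <- genCov(cov)
  Ainv <- aInverse(ped, inbreeding = inbreeding, groups = groups)
  units <- rownames(Ainv)          # animals then group columns
  J <- length(traits)
  parity <- if ("parity" %in% colnames(ph)) ph$parity else rep(1L, nrow(ph))
  recKey <- paste(ph$animal, parity, sep = "\r")
  recs <- split(seq_len(nrow(ph)), recKey)

  ## fixed-effect column labels, per trait
  ## one column per observed (trait, level) combination only, so no
  ## fixed equation is empty
  fixedLabels <- character(0)
  if ("hys" %in% fixed && nrow(ph)) {
    cmb <- unique(paste("hys", ph$trait, ph$hys, sep = ":"))
    fixedLabels <- c(fixedLabels, sort(cmb))
  }
  if ("parity" %in% fixed && nrow(ph)) {
    later <- parity > min(parity)
    if (any(later)) {
      cmb <- unique(paste("parity", ph$trait[later], parity[later], sep = ":"))
      fixedLabels <- c(fixedLabels, sort(cmb))
    }
  }
  nf <- length(fixedLabels)
  fIdx <- setNames(seq_len(nf), fixedLabels)
  gCol <- function(animal, t) nf + (match(animal, units) - 1L) * J + t
  nEq <- nf + length(units) * J

  trip <- vector("list", length(recs))
  rhs <- numeric(nEq)
  for (k in seq_along(recs)) {
    rr <- recs[[k]]
    obs <- match(ph$trait[rr], traits)
    o <- order(obs); rr <- rr[o]; obs <- obs[o]
    if (anyDuplicated(obs)) stop("duplicate trait within one record")
    Rinv <- solve(E[obs, obs, drop = FALSE])
    cols <- vector("list", length(obs))
    for (a in seq_along(obs)) {
      t <- obs[a]; row <- rr[a]
      cl <- gCol(ph$animal[row], t)
      if ("hys" %in% fixed)
        cl <- c(fIdx[[paste("hys", traits[t], ph$hys[row], sep = ":")]], cl)
      if ("parity" %in% fixed && parity[row] > min(parity))
        cl <- c(fIdx[[paste("parity", traits[t], parity[row], sep = ":")]], cl)
      cols[[a]] <- cl
    }
    y <- ph$value[rr]
    li <- integer(0); lj <- integer(0); lx <- numeric(0)
    for (a in seq_along(obs)) {
      for (b in seq_along(obs)) {
        w <- Rinv[a, b]
        if (w == 0) next
        grid <- expand.grid(u = cols[[a]], v = cols[[b]])
        li <- c(li, grid$u); lj <- c(lj, grid$v)
        lx <- c(lx, rep(w, nrow(grid)))
      }
      rhs[cols[[a]]] <- rhs[cols[[a]]] + sum(Rinv[a, ] * y)
    }
    trip[[k]] <- list(i = li, j = lj, x = lx)
  }
  C <- Matrix::sparseMatrix(
    i = unlist(lapply(trip, `[[`, "i")) %||% integer(0),
    j = unlist(lapply(trip, `[[`, "j")) %||% integer(0),
    x = unlist(lapply(trip, `[[`, "x")) %||% numeric(0),
    dims = c(nEq, nEq))
  ## genetic prior block
  Ginv <- solve(G)
  prior <- Matrix::kronecker(Ainv, Matrix::Matrix(Ginv, sparse = TRUE))
  pad <- function(m) {
    if (nf == 0L) return(m)
    Matrix::bdiag(Matrix::Matrix(0, nf, nf, sparse = TRUE), m)
  }
  C <- C + pad(prior)
  nGroups <- length(units) - length(ped@id)
  if (nGroups > 0L) {
    gEq <- nf + (length(ped@id) * J + 1L):(length(units) * J)
    ridge <- 1e-8 * mean(Matrix::diag(C)[seq_len(nf + length(ped@id) * J)])
    C <- C + Matrix::sparseMatrix(i = gEq, j = gEq, x = ridge,
                                  dims = c(nEq, nEq))
  }
  list(C = Matrix::forceSymmetric(C), rhs = rhs, fixedLabels = fixedLabels,
       units = units, animals = ped@id, traits = traits, nf = nf, J = J)
}

#' Solve the mixed-model equations
#'
#' Direct sparse factorization (deterministic) or Jacobi-preconditioned
#' conjugate gradients. The CG solver stops when the residual norm
#' drops below `tol` times the right-hand-side norm and errors out if
#' the limit is hit, reporting the last residual.
#'
#' @param mme Output of [buildMME()].
#' @param method "direct" or "cg".
#' @param tol,maxIter CG controls.
#' @return List with `solution`, named `fixed` estimates and the `ebv`
#'   animal x trait matrix (group columns excluded).
#' @export
solveMME <- function(mme, method = c("direct", "cg"), tol = 1e-10,
                     maxIter = 10000L) {
  method <- match.arg(method)
  C <- mme$C; b <- mme$rhs
  if (method == "direct") {
    x <- as.numeric(Matrix::solve(C, b))
  } else {
    x <- .cgSolve(C, b, tol = tol, maxIter = maxIter)
  }
  nf <- mme$nf; J <- mme$J
  nAnim <- length(mme$animals)
  ebv <- matrix(x[nf + seq_len(nAnim * J)], nAnim, J, byrow = TRUE,
                dimnames = list(mme$animals, mme$traits))
  fixed <- if (nf) setNames(x[seq_len(nf)], mme$fixedLabels) else numeric(0)
  list(solution = x, fixed = fixed, ebv = ebv)
}

.cgSolve <- function(C, b, tol = 1e-10, maxIter = 10000L) {
  dg <- Matrix::diag(C)
  dg[dg <= 0] <- 1
  x <- numeric(length(b))
  r <- b - as.numeric(C %*% x)
  z <- r / dg
  p <- z
  rz <- sum(r * z)
  bn <- sqrt(sum(b^2))
  if (bn == 0) return(x)
  for (it in seq_len(maxIter)) {
    Cp <- as.numeric(C %*% p)
    alpha <- rz / sum(p * Cp)
    x <- x + alpha * p
    r <- r - alpha * Cp
    if (sqrt(sum(r^2)) <= tol * bn) return(x)
    z <- r / dg
    rzNew <- sum(r * z)
    beta <- rzNew / rz
    rz <- rzNew
    p <- z + beta * p
  }
  stop("conjugate gradient did not converge in ", maxIter,
       " iterations (residual ", format(sqrt(sum(r^2)) / bn), ")")
}

#' Exact reliabilities from the inverse coefficient matrix
#'
#' r2 = 1 - PEV / g_tt, with the prediction-error variance taken from
#' the diagonal of the dense inverse of the MME coefficient matrix.
#' Exact, but only feasible at desk scale; systems above `maxEquations`
#' are refused (subset the data instead).
#'
#' @param mme Output of [buildMME()].
#' @param cov The [TraitCovariances-class] used to build the system.
#' @param maxEquations Dense-inversion guard.
#' @return Animal x trait matrix of reliabilities in [0, 1).
#' @export
reliability <- function(mme, cov, maxEquations = 4000L) {
  nEq <- nrow(mme$C)
  if (nEq > maxEquations)
    stop(nEq, " equations exceed the dense-inversion limit of ",
         maxEquations, "; compute reliabilities on a subset")
  Cinv <- solve(as.matrix(mme$C))
  G <- genCov(cov)
  nAnim <- length(mme$animals); J <- mme$J
  idx <- mme$nf + seq_len(nAnim * J)
  pev <- matrix(diag(Cinv)[idx], nAnim, J, byrow = TRUE,
                dimnames = list(mme$animals, mme$traits))
  r2 <- 1 - sweep(pev, 2L, diag(G), "/")
  pmin(pmax(r2, 0), 1 - 1e-12)
}

#' Rebase EBVs to a genetic-base cohort
#'
#' Subtracts the cohort's per-trait mean EBV, so the base cohort
#' averages zero for every trait (e.g. the mean EBV of calves born in a
#' chosen year). Idempotent.
#'
#' @param ebv Animal x trait EBV matrix with animal rownames.
#' @param cohort Character ids or logical/integer row selector; must be
#'   non-empty.
#' @return The rebased matrix, with the cohort recorded in attribute
#'   `"baseCohort"`.
#' @export
rebase <- function(ebv, cohort) {
  rows <- if (is.character(cohort)) match(cohort, rownames(ebv)) else
    which(rep_len(TRUE, nrow(ebv)))[cohort]
  rows <- rows[!is.na(rows)]
  if (!length(rows)) stop("empty base cohort")
  out <- sweep(ebv, 2L, colMeans(ebv[rows, , drop = FALSE]))
  attr(out, "baseCohort") <- rownames(ebv)[rows]
  out
}

#' Combine per-parity evaluations into a multi-parity index
#'
#' Weighted sum of per-parity EBVs with weights normalized to one;
#' negative weights are rejected.
#'
#' @param ebvByParity Animal x parity matrix (or a list of equal-length
#'   vectors, one per parity).
#' @param weights Non-negative weights, one per parity. The default
#'   (0.5, 0.3, 0.2) favors early parities; national weights are not
#'   published, so these are configurable.
#' @return Named numeric vector, one combined value per animal.
#' @export
combineParities <- function(ebvByParity, weights = c(0.5, 0.3, 0.2)) {
  if (is.list(ebvByParity)) ebvByParity <- do.call(cbind, ebvByParity)
  if (any(weights < 0)) stop("negative parity weights are not allowed")
  if (sum(weights) == 0) stop("weights sum to zero")
  weights <- rep_len(weights, ncol(ebvByParity))
  drop(ebvByParity %*% (weights / sum(weights)))
}

#' Realized genetic trends
#'
#' Per-trait ordinary least-squares regression of EBV on birth date
#' (decimal years), the standard estimate of the realized genetic trend;
#' returns the slope and its standard error in trait units per year.
#'
#' @param ebvTable data.frame(animal, trait, ebv, birth).
#' @return data.frame(trait, slope, se, n).
#' @export
realizedTrends <- function(ebvTable) {
  if (length(unique(ebvTable$birth)) < 3L)
    stop("need at least three distinct birth dates for a trend")
  yr <- decimalYear(ebvTable$birth)
  out <- lapply(split(seq_len(nrow(ebvTable)), ebvTable$trait), function(idx) {
    fit <- lm(ebvTable$ebv[idx] ~ yr[idx])
    ## summary warns on an exactly collinear fit; the zero SE is valid
    sm <- suppressWarnings(summary(fit))$coefficients
    se <- if (nrow(sm) > 1L && !is.na(sm[2L, 2L])) sm[2L, 2L] else 0
    data.frame(trait = ebvTable$trait[idx[1L]],
               slope = unname(coef(fit)[2L]), se = se, n = length(idx),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-call genetic evaluation
#'
#' Builds and solves the MME, optionally computes exact reliabilities
#' and rebases to a base cohort, returning an
#' [EvaluationResult-class].
#'
#' @inheritParams buildMME
#' @param method Solver passed to [solveMME()].
#' @param reliabilities Compute exact PEV reliabilities (desk scale
#'   only).
#' @param baseCohort Optional ids (or a birth-year integer, selecting
#'   the calves born that year) defining the genetic base.
#' @return An [EvaluationResult-class].
#' @export
blupEvaluate <- function(phenotypes, ped, cov,
                         fixed = intersect(c("hys", "parity"),
                                           colnames(phenotypes)),
                         groups = NULL, method = "direct",
                         reliabilities = FALSE, baseCohort = NULL) {
  mme <- buildMME(phenotypes, ped, cov, fixed = fixed, groups = groups)
  sol <- solveMME(mme, method = method)
  ebvM <- sol$ebv
  base <- character(0)
  if (!is.null(baseCohort)) {
    if (is.numeric(baseCohort) && length(baseCohort) == 1L)
      baseCohort <- ped@id[!is.na(ped@birth) &
                           as.integer(format(ped@birth, "%Y")) == baseCohort]
    ebvM <- rebase(ebvM, baseCohort)
    base <- attr(ebvM, "baseCohort")
  }
  rel <- if (reliabilities) reliability(mme, cov) else NULL
  new("EvaluationResult", ebv = ebvM, reliability = rel,
      fixedSolutions = sol$fixed, baseCohort = base)
}
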