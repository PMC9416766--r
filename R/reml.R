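## Multi-trait REML for the animal model. The restricted likelihood is
## evaluated in the eigenbasis of the relationship matrix among the
## phenotyped animals (the exact marginal form of the individual animal
## model: unphenotyped relatives integrate out of the likelihood), which
## turns the n x n covariance into independent J x J blocks per
## eigencomponent. EM updates are monotone in the restricted likelihood;
## average-information (AI) updates are quasi-Newton with approximate
## standard errors from the inverse AI matrix.

# ---- parameter packing -------------------------------------------------

.vech <- function(m) m[lower.tri(m, diag = TRUE)]

.unvech <- function(v, J, labels = NULL) {
  m <- matrix(0, J, J)
  m[lower.tri(m, diag = TRUE)] <- v
  m <- m + t(m) - diag(diag(m), J)
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

# symmetric basis matrix for parameter (a, b)
.symBasis <- function(a, b, J) {
  S <- matrix(0, J, J)
  S[a, b] <- S[a, b] + 1
  S[b, a] <- S[b, a] + 1
  if (a == b) S[a, b] <- 1
  S
}

# ---- spectral preparation ---------------------------------------------

# Connected components of the nonzero pattern of a symmetric matrix.
.components <- function(K) {
  n <- nrow(K)
  Kt <- methods::as(methods::as(Matrix::drop0(Matrix::Matrix(K, sparse = TRUE),
                                              tol = 1e-12), "generalMatrix"),
                    "TsparseMatrix")
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ii <- Kt@i + 1L; jj <- Kt@j + 1L
  for (k in seq_along(ii)) {
    a <- find(ii[k]); b <- find(jj[k])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(n), find, 1L)
  split(seq_len(n), comp)
}

# Eigen-decompose K blockwise; rotate Y and X into the eigenbasis.
.spectralPrep <- function(Y, X, K) {
  blocks <- .components(K)
  n <- nrow(Y)
  d <- numeric(n)
  Yt <- matrix(0, n, ncol(Y))
  Xt <- matrix(0, n, ncol(X))
  pos <- 0L
  Kd <- as.matrix(K)
  for (idx in blocks) {
    m <- length(idx)
    rows <- pos + seq_len(m)
    if (m == 1L) {
      d[rows] <- Kd[idx, idx]
      Yt[rows, ] <- Y[idx, , drop = FALSE]
      Xt[rows, ] <- X[idx, , drop = FALSE]
    } else {
      eg <- eigen(Kd[idx, idx], symmetric = TRUE)
      d[rows] <- eg$values
      Yt[rows, ] <- crossprod(eg$vectors, Y[idx, , drop = FALSE])
      Xt[rows, ] <- crossprod(eg$vectors, X[idx, , drop = FALSE])
    }
    pos <- pos + m
  }
  d[d < 0 & d > -1e-8] <- 0
  if (any(d < 0)) stop("relationship matrix is not positive semi-definite")
  if (ncol(Y) == 1L)  # single trait: fully vectorized path, no grouping
    return(list(d = d, Yt = Yt, Xt = Xt))
  ## group rows sharing an eigenvalue: one J x J algebra step per group
  key <- signif(d, 10)
  ord <- split(seq_len(n), key)
  groups <- lapply(ord, function(rows) {
    Xg <- Xt[rows, , drop = FALSE]
    list(d = d[rows[1L]], n = length(rows), X = Xg, Y = Yt[rows, , drop = FALSE],
         XtX = crossprod(Xg))
  })
  groups
}

# ---- single-trait vectorized path -------------------------------------

.remlEval1 <- function(sp, sg, se) {
  v <- sp$d * sg + se
  if (any(v <= 0)) stop("non-positive variance encountered")
  w <- 1 / v
  y <- sp$Yt[, 1L]
  M <- crossprod(sp$Xt, sp$Xt * w)
  beta <- solve(M, crossprod(sp$Xt, w * y))
  r <- y - as.numeric(sp$Xt %*% beta)
  f <- r * w
  ll <- -0.5 * (sum(log(v)) +
                as.numeric(determinant(M, logarithm = TRUE)$modulus) +
                sum(r * f))
  Q <- rowSums((sp$Xt %*% solve(M)) * sp$Xt)   # x' Minv x per component
  pkk <- w - w^2 * Q
  list(ll = ll, w = w, f = f, M = M,
       S0 = sum(f^2), S1 = sum(sp$d * f^2),
       T0 = sum(pkk), T1 = sum(sp$d * pkk))
}

.aiPieces1 <- function(sp, ev) {
  w <- ev$w; f <- ev$f; d <- sp$d
  ag <- crossprod(sp$Xt, w * (d * f))
  ae <- crossprod(sp$Xt, w * f)
  Minv <- solve(ev$M)
  plain <- matrix(c(sum(w * d^2 * f^2), sum(w * d * f^2),
                    sum(w * d * f^2), sum(w * f^2)), 2L)
  corr <- rbind(cbind(crossprod(ag, Minv %*% ag), crossprod(ag, Minv %*% ae)),
                cbind(crossprod(ae, Minv %*% ag), crossprod(ae, Minv %*% ae)))
  AI <- 0.5 * (plain - corr)
  score <- 0.5 * c(ev$S1 - ev$T1, ev$S0 - ev$T0)
  list(score = score, AI = AI, nb = 1L)
}

.spectralReml1 <- function(sp, init, method, tol, maxIter, emWarmup,
                           floorRel, labels) {
  n <- length(sp$d)
  sg <- init$G[1L, 1L]; se <- init$E[1L, 1L]
  scale0 <- sg + se
  floorV <- function(x) max(x, floorRel * scale0)
  ev <- .remlEval1(sp, sg, se)
  llTrace <- ev$ll
  converged <- FALSE
  iter <- 0L
  seG <- seE <- NULL
  while (iter < maxIter) {
    iter <- iter + 1L
    useEM <- method == "em" || (method == "em-then-ai" && iter <= emWarmup)
    if (useEM) {
      sgn <- floorV(sg + sg^2 * (ev$S1 - ev$T1) / n)
      sen <- floorV(se + se^2 * (ev$S0 - ev$T0) / n)
      evn <- .remlEval1(sp, sgn, sen)
    } else {
      pieces <- .aiPieces1(sp, ev)
      AIr <- pieces$AI + diag(1e-10 * max(diag(pieces$AI)), 2L)
      step <- tryCatch(solve(AIr, pieces$score),
                       error = function(e) pieces$score / max(diag(AIr)))
      lambda <- 1
      repeat {
        sgn <- floorV(sg + lambda * step[1L])
        sen <- floorV(se + lambda * step[2L])
        evn <- tryCatch(.remlEval1(sp, sgn, sen), error = function(e) NULL)
        if (!is.null(evn) && evn$ll >= ev$ll - 1e-8) break
        lambda <- lambda / 2
        if (lambda < 1e-6) {
          sgn <- floorV(sg + sg^2 * (ev$S1 - ev$T1) / n)
          sen <- floorV(se + se^2 * (ev$S0 - ev$T0) / n)
          evn <- .remlEval1(sp, sgn, sen)
          break
        }
      }
    }
    delta <- max(abs(c(sgn - sg, sen - se))) / (sg + se)
    sg <- sgn; se <- sen; ev <- evn
    llTrace <- c(llTrace, ev$ll)
    if (delta < tol && !(method == "em-then-ai" && iter <= emWarmup)) {
      converged <- TRUE
      break
    }
  }
  if (method %in% c("ai", "em-then-ai")) {
    pieces <- .aiPieces1(sp, ev)
    Vc <- tryCatch(solve(pieces$AI), error = function(e) NULL)
    if (!is.null(Vc)) {
      sev <- sqrt(pmax(diag(Vc), 0))
      seG <- matrix(sev[1L], dimnames = list(labels, labels))
      seE <- matrix(sev[2L], dimnames = list(labels, labels))
    }
  }
  list(G = matrix(sg, dimnames = list(labels, labels)),
       E = matrix(se, dimnames = list(labels, labels)),
       seG = seG, seE = seE, logLik = llTrace, converged = converged,
       iterations = iter)
}

# ---- likelihood and updates -------------------------------------------

# Evaluate the restricted likelihood and the sufficient statistics for
# the EM and AI updates at (G, E).
.remlEval <- function(groups, G, E, p, J) {
  pJ <- p * J
  M <- matrix(0, pJ, pJ)
  rhs <- numeric(pJ)
  logdetV <- 0
  for (g in groups) {
    Vg <- g$d * G + E
    Vinv <- solve(Vg)
    ld <- determinant(Vg, logarithm = TRUE)
    logdetV <- logdetV + g$n * as.numeric(ld$modulus)
    M <- M + kronecker(g$XtX, Vinv)
    rhs <- rhs + as.vector(t(crossprod(g$X, g$Y %*% Vinv)))
  }
  beta <- solve(M, rhs)
  B <- t(matrix(beta, J, p))
  quad <- 0
  Fs <- vector("list", length(groups))
  Vinvs <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    Vinv <- solve(g$d * G + E)
    R <- g$Y - g$X %*% B
    Fg <- R %*% Vinv
    quad <- quad + sum(R * Fg)
    Fs[[i]] <- Fg
    Vinvs[[i]] <- Vinv
  }
  logdetM <- as.numeric(determinant(M, logarithm = TRUE)$modulus)
  ll <- -0.5 * (logdetV + logdetM + quad)
  list(ll = ll, M = M, B = B, Fs = Fs, Vinvs = Vinvs)
}

# One EM-REML update of (G, E) given an evaluation.
.emUpdate <- function(groups, ev, G, E, p, J, floorRel = 1e-8) {
  n <- sum(vapply(groups, `[[`, 0, "n"))
  Minv <- solve(ev$M)
  A4 <- array(Minv, c(J, p, J, p))
  S0 <- matrix(0, J, J); S1 <- matrix(0, J, J)
  T0 <- matrix(0, J, J); T1 <- matrix(0, J, J)
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    Fg <- ev$Fs[[i]]; Vinv <- ev$Vinvs[[i]]
    FF <- crossprod(Fg)
    S0 <- S0 + FF
    S1 <- S1 + g$d * FF
    Cg <- matrix(0, J, J)
    for (a in seq_len(J)) for (b in seq_len(J))
      Cg[a, b] <- sum(g$XtX * A4[a, , b, ])
    Pg <- g$n * Vinv - Vinv %*% Cg %*% Vinv
    T0 <- T0 + Pg
    T1 <- T1 + g$d * Pg
  }
  Gn <- floorPSD(G + (G %*% (S1 - T1) %*% G) / n, floorRel)
  En <- floorPSD(E + (E %*% (S0 - T0) %*% E) / n, floorRel)
  dimnames(Gn) <- dimnames(G); dimnames(En) <- dimnames(E)
  list(G = Gn, E = En)
}

# Score vector and average-information matrix over theta = (vech G, vech E).
.aiPieces <- function(groups, ev, p, J) {
  basis <- list()
  for (b in seq_len(J)) for (a in b:J) basis <- c(basis, list(.symBasis(a, b, J)))
  nb <- length(basis)
  npar <- 2L * nb
  pJ <- p * J
  Minv <- solve(ev$M)
  A4 <- array(Minv, c(J, p, J, p))
  quadv <- numeric(npar)
  trv <- numeric(npar)
  AIplain <- matrix(0, npar, npar)
  avec <- matrix(0, pJ, npar)
  T0 <- matrix(0, J, J); T1 <- matrix(0, J, J)
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    Fg <- ev$Fs[[i]]; Vinv <- ev$Vinvs[[i]]
    Cg <- matrix(0, J, J)
    for (a in seq_len(J)) for (b in seq_len(J))
      Cg[a, b] <- sum(g$XtX * A4[a, , b, ])
    Pg <- g$n * Vinv - Vinv %*% Cg %*% Vinv
    T0 <- T0 + Pg; T1 <- T1 + g$d * Pg
    Ws <- vector("list", npar)
    for (m in seq_len(nb)) {
      Ws[[m]] <- g$d * (Fg %*% basis[[m]])       # G parameters
      Ws[[nb + m]] <- Fg %*% basis[[m]]          # E parameters
    }
    for (m in seq_len(npar)) {
      WmV <- Ws[[m]] %*% Vinv
      quadv[m] <- quadv[m] + sum(Ws[[m]] * Fg)
      avec[, m] <- avec[, m] + as.vector(t(crossprod(g$X, WmV)))
      for (mm in m:npar)
        AIplain[m, mm] <- AIplain[m, mm] + sum(WmV * Ws[[mm]])
    }
  }
  for (m in seq_len(nb)) {
    trv[m] <- sum(T1 * basis[[m]])
    trv[nb + m] <- sum(T0 * basis[[m]])
  }
  AIplain <- AIplain + t(AIplain) - diag(diag(AIplain))
  AI <- 0.5 * (AIplain - t(avec) %*% Minv %*% avec)
  score <- 0.5 * (quadv - trv)
  list(score = score, AI = AI, nb = nb)
}

# Core iteration loop shared by remlFit and the genomic null model.
.spectralReml <- function(Y, X, K, init = NULL,
                          method = c("em-then-ai", "em", "ai"),
                          tol = 1e-6, maxIter = 200L, emWarmup = 10L,
                          floorRel = 1e-8) {
  method <- match.arg(method)
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  J <- ncol(Y); p <- ncol(X)
  labels <- colnames(Y)
  if (qr(X)$rank < p) stop("fixed-effect design is rank deficient")
  if (is.null(init)) {
    S <- cov(Y)
    init <- list(G = 0.4 * S, E = 0.6 * S)
  }
  G <- symmetrize(as.matrix(init$G)); E <- symmetrize(as.matrix(init$E))
  dimnames(G) <- dimnames(E) <- list(labels, labels)
  if (J == 1L) {
    sp <- .spectralPrep(Y, X, K)
    return(.spectralReml1(sp, list(G = G, E = E), method, tol, maxIter,
                          emWarmup, floorRel, labels))
  }
  groups <- .spectralPrep(Y, X, K)
  llTrace <- numeric(0)
  converged <- FALSE
  seG <- seE <- NULL
  iter <- 0L
  ev <- .remlEval(groups, G, E, p, J)
  llTrace <- ev$ll
  while (iter < maxIter) {
    iter <- iter + 1L
    useEM <- method == "em" ||
      (method == "em-then-ai" && iter <= emWarmup)
    thetaOld <- c(.vech(G), .vech(E))
    if (useEM) {
      upd <- .emUpdate(groups, ev, G, E, p, J, floorRel)
      Gn <- upd$G; En <- upd$E
      evn <- .remlEval(groups, Gn, En, p, J)
    } else {
      pieces <- .aiPieces(groups, ev, p, J)
      AI <- pieces$AI
      ## ridge for safety far from the optimum
      AIr <- AI + diag(1e-10 * max(diag(AI)), nrow(AI))
      step <- tryCatch(solve(AIr, pieces$score),
                       error = function(e) pieces$score / max(diag(AIr)))
      lambda <- 1
      repeat {
        theta <- thetaOld + lambda * step
        nb <- pieces$nb
        Gn <- floorPSD(.unvech(theta[seq_len(nb)], J, labels), floorRel)
        En <- floorPSD(.unvech(theta[nb + seq_len(nb)], J, labels), floorRel)
        evn <- tryCatch(.remlEval(groups, Gn, En, p, J),
                        error = function(e) NULL)
        if (!is.null(evn) && evn$ll >= ev$ll - 1e-8) break
        lambda <- lambda / 2
        if (lambda < 1e-6) {  # fall back to an EM step
          upd <- .emUpdate(groups, ev, G, E, p, J, floorRel)
          Gn <- upd$G; En <- upd$E
          evn <- .remlEval(groups, Gn, En, p, J)
          break
        }
      }
    }
    thetaNew <- c(.vech(Gn), .vech(En))
    scale <- mean(abs(thetaOld)) + 1e-12
    delta <- max(abs(thetaNew - thetaOld) / (abs(thetaOld) + scale))
    G <- Gn; E <- En; ev <- evn
    llTrace <- c(llTrace, ev$ll)
    if (delta < tol &&
        !(method == "em-then-ai" && iter <= emWarmup)) {
      converged <- TRUE
      break
    }
  }
  if (method %in% c("ai", "em-then-ai")) {
    pieces <- .aiPieces(groups, ev, p, J)
    Vc <- tryCatch(solve(pieces$AI), error = function(e) NULL)
    if (!is.null(Vc)) {
      se <- sqrt(pmax(diag(Vc), 0))
      nb <- pieces$nb
      seG <- .unvech(se[seq_len(nb)], J, labels)
      seE <- .unvech(se[nb + seq_len(nb)], J, labels)
    }
  }
  list(G = G, E = E, seG = seG, seE = seE, logLik = llTrace,
       converged = converged, iterations = iter)
}

# ---- user-facing fit ---------------------------------------------------

#' Multi-trait REML variance components for the animal model
#'
#' Estimates the genetic and environmental covariance matrices among the
#' requested traits from phenotyped animals related through the
#' pedigree, for the model record = fixed effects + additive genetic
#' effect + residual. Animals with incomplete trait records are dropped
#' (the multi-trait analysis is complete-case, mirroring the national
#' variance-component data sets). With several parities, each
#' trait-parity combination is treated as a separate trait.
#'
#' `method = "em"` gives monotone (but slow near a variance boundary)
#' EM-REML; `"ai"` gives average-information quasi-Newton updates with
#' approximate standard errors; the default `"em-then-ai"` runs a few EM
#' warm-up rounds before switching, the standard remedy for AI
#' divergence far from the optimum. PSD is enforced at each iterate by
#' eigenvalue flooring at `1e-8` times the trace.
#'
#' @param phenotypes Long data.frame(animal, trait, value) with optional
#'   parity and hys columns.
#' @param ped A [Pedigree-class] covering the phenotyped animals.
#' @param traits Traits to analyze (default: all present).
#' @param parities Parities to include (default 1; several parities
#'   switch on parity-as-trait).
#' @param fixed "mean" for an overall mean per trait or "hys" for
#'   herd-year-season class effects.
#' @param init Optional list(G =, E =) starting values.
#' @param method "em-then-ai" (default), "em" or "ai".
#' @param tol Convergence tolerance on the maximum relative parameter
#'   change.
#' @param maxIter,emWarmup Iteration limits.
#' @param maxAnimals Dense guard passed to [tabularA()].
#' @return A [RemlFit-class]; non-convergence is flagged, with the last
#'   iterate returned.
#' @export
remlFit <- function(phenotypes, ped, traits = NULL, parities = 1L,
                    fixed = c("mean", "hys"), init = NULL,
                    method = c("em-then-ai", "em", "ai"), tol = 1e-6,
                    maxIter = 200L, emWarmup = 10L, maxAnimals = 5000L) {
  fixed <- match.arg(fixed)
  method <- match.arg(method)
  ph <- phenotypes
  if ("parity" %in% colnames(ph)) ph <- ph[ph$parity %in% parities, ]
  if (!is.null(traits)) ph <- ph[ph$trait %in% traits, ]
  if (length(parities) > 1L)
    ph$trait <- paste(ph$trait, ph$parity, sep = "_p")
  traitLv <- unique(ph$trait)
  wide <- .toWide(ph, traitLv)
  Y <- wide$Y
  if (nrow(Y) < 2L) stop("fewer than two complete records")
  if (fixed == "hys") {
    if (!"hys" %in% colnames(ph)) stop("no hys column in the phenotypes")
    hys <- ph$hys[match(rownames(Y), ph$animal)]
    X <- model.matrix(~ 0 + factor(hys))
  } else {
    X <- matrix(1, nrow(Y), 1L)
  }
  A <- tabularA(ped, maxAnimals = maxAnimals)
  K <- A[rownames(Y), rownames(Y)]
  res <- .spectralReml(Y, X, K, init = init, method = method, tol = tol,
                       maxIter = maxIter, emWarmup = emWarmup)
  se <- if (!is.null(res$seG)) list(G = res$seG, E = res$seE) else NULL
  new("RemlFit",
      covariances = traitCovariances(res$G, res$E, se = se),
      logLik = res$logLik, converged = res$converged,
      iterations = res$iterations, method = method)
}

# long (animal, trait, value) -> complete-case wide matrix
.toWide <- function(ph, traitLv) {
  animals <- unique(ph$animal)
  Y <- matrix(NA_real_, length(animals), length(traitLv),
              dimnames = list(animals, traitLv))
  Y[cbind(match(ph$animal, animals), match(ph$trait, traitLv))] <- ph$value
  keep <- complete.cases(Y)
  list(Y = Y[keep, , drop = FALSE])
}

# ---- derived genetic parameters ---------------------------------------

#' Heritability of a trait
#'
#' h2 = G_tt / (G_tt + E_tt).
#'
#' @param cov A [TraitCovariances-class].
#' @param trait Trait label or index.
#' @return Scalar in [0, 1].
#' @examples
#' heritability(ilTraitCovariances(), "protein")  # 0.45
#' @export
heritability <- function(cov, trait) {
  tot <- genCov(cov)[trait, trait] + envCov(cov)[trait, trait]
  if (tot <= 0) stop("zero total variance: heritability undefined")
  genCov(cov)[trait, trait] / tot
}

#' Genetic, environmental and phenotypic correlations
#'
#' r = C_ab / sqrt(C_aa C_bb) for the genetic (G), environmental (E) or
#' phenotypic (P = G + E) covariance matrix.
#'
#' @param cov A [TraitCovariances-class].
#' @param a,b Trait labels or indices.
#' @return Scalar correlation in [-1, 1].
#' @examples
#' geneticCorrelation(ilTraitCovariances(), "protein", "cs")  # -0.38
#' @export
geneticCorrelation <- function(cov, a, b) .corOf(genCov(cov), a, b)

#' @rdname geneticCorrelation
#' @export
environmentalCorrelation <- function(cov, a, b) .corOf(envCov(cov), a, b)

#' @rdname geneticCorrelation
#' @export
phenotypicCorrelation <- function(cov, a, b) .corOf(phenCov(cov), a, b)

.corOf <- function(C, a, b) {
  va <- C[a, a]; vb <- C[b, b]
  if (va <= 0 || vb <= 0) stop("zero variance: correlation undefined")
  max(-1, min(1, C[a, b] / sqrt(va * vb)))
}

#' Genetic-parameter matrix in the conventional layout
#'
#' Square trait x trait matrix with heritabilities on the diagonal,
#' genetic correlations above it, and environmental (default) or
#' phenotypic correlations below it -- the layout in which national
#' REML analyses are reported.
#'
#' @param cov A [TraitCovariances-class].
#' @param below "environmental" or "phenotypic" for the sub-diagonal.
#' @return Numeric matrix with trait dimnames.
#' @export
parameterMatrix <- function(cov, below = c("environmental", "phenotypic")) {
  below <- match.arg(below)
  tr <- traitNames(cov)
  J <- length(tr)
  out <- matrix(0, J, J, dimnames = list(tr, tr))
  lowC <- if (below == "environmental") envCov(cov) else phenCov(cov)
  for (i in seq_len(J)) {
    out[i, i] <- heritability(cov, tr[i])
    for (j in seq_len(J)) {
      if (j > i) out[i, j] <- geneticCorrelation(cov, tr[i], tr[j])
      if (j < i) out[i, j] <- .corOf(lowC, tr[i], tr[j])
    }
  }
  out
}
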