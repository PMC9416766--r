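## Mixed-model association on sire evaluations: marker QC, IBS kinship,
## single-component genomic REML (pseudo-heritability), two-stage
## generalized-least-squares scan with variance components fixed at the
## null estimates, Bonferroni correction and cross-trait marker-effect
## comparison.

#' Per-SNP call rate and minor allele frequency
#'
#' MAF is folded to [0, 0.5] and computed over non-missing calls.
#'
#' @param gm A [GenotypeMatrix-class].
#' @return Named numeric vector.
#' @export
snpMaf <- function(gm) {
  D <- dosages(gm)
  p <- colMeans(D, na.rm = TRUE) / 2
  setNames(pmin(p, 1 - p), colnames(D))
}

#' @rdname snpMaf
#' @export
snpCallRate <- function(gm) {
  D <- dosages(gm)
  setNames(colMeans(!is.na(D)), colnames(D))
}

#' Filter SNPs on call rate
#'
#' Retains SNPs genotyped in more than `minCallRate` of the cohort
#' (strict inequality, matching the ">90% of the tested cohort"
#' convention) and reports the count removed.
#'
#' @param gm A [GenotypeMatrix-class].
#' @param minCallRate Call-rate threshold (default 0.90).
#' @return The filtered [GenotypeMatrix-class].
#' @export
qcFilter <- function(gm, minCallRate = 0.90) {
  cr <- snpCallRate(gm)
  keep <- cr > minCallRate
  if (!any(keep)) stop("no SNP passes the call-rate filter")
  message(sum(!keep), " of ", length(keep),
          " SNPs removed at call rate <= ", minCallRate)
  genotypeMatrix(dosages(gm)[, keep, drop = FALSE],
                 map = snpMap(gm)[keep, , drop = FALSE],
                 causal = gm@causal)
}

#' Identity-by-state kinship matrix
#'
#' K_ij is the mean over SNPs of the IBS share 1 - |d_i - d_j| / 2,
#' computed over the SNPs called in both individuals. Symmetric, with
#' unit diagonal for complete data; a pair with no overlapping SNPs is
#' an error.
#'
#' @param gm A [GenotypeMatrix-class].
#' @return Individuals x individuals similarity matrix.
#' @export
ibsKinship <- function(gm) {
  D <- dosages(gm)
  called <- !is.na(D)
  I0 <- (D == 0) & called; I1 <- (D == 1) & called; I2 <- (D == 2) & called
  I0[is.na(I0)] <- FALSE; I1[is.na(I1)] <- FALSE; I2[is.na(I2)] <- FALSE
  storage.mode(I0) <- storage.mode(I1) <- storage.mode(I2) <- "double"
  shared <- tcrossprod(called * 1)
  if (any(shared == 0))
    stop("some pair of individuals shares no called SNP")
  absdiff <- tcrossprod(I0, I1) + tcrossprod(I1, I0) +
    tcrossprod(I1, I2) + tcrossprod(I2, I1) +
    2 * (tcrossprod(I0, I2) + tcrossprod(I2, I0))
  K <- 1 - absdiff / (2 * shared)
  dimnames(K) <- list(rownames(D), rownames(D))
  K
}

#' Genomic REML and pseudo-heritability
#'
#' Fits y = mean (+ covariates) + g + e with cov(g) proportional to the
#' kinship matrix K, by single-component REML in the eigenbasis of K,
#' and returns the fraction of variance attached to K -- the
#' pseudo-heritability.
#'
#' @param y Phenotype vector (one value per row of K).
#' @param K Kinship/similarity matrix (PSD up to flooring).
#' @param covariates Optional numeric matrix of fixed covariates (an
#'   intercept is always included).
#' @param ... Passed to the REML iterator (tol, maxIter, method, ...).
#' @return List with `h2`, `varG`, `varE` and the full `fit`.
#' @export
pseudoHeritability <- function(y, K, covariates = NULL, ...) {
  y <- as.numeric(y)
  n <- length(y)
  X <- cbind(rep(1, n), covariates)
  vy <- var(y)
  fit <- .spectralReml(matrix(y, ncol = 1L), X, K,
                       init = list(G = matrix(vy / 2), E = matrix(vy / 2)),
                       ...)
  vg <- fit$G[1L, 1L]; ve <- fit$E[1L, 1L]
  list(h2 = vg / (vg + ve), varG = vg, varE = ve, fit = fit)
}

#' Mixed-model association scan
#'
#' Two-stage scan in the EMMAX style: variance components of
#' y = mean + g + e, cov(g) = s2g K, cov(e) = s2e I are estimated once
#' under the null, then each SNP is tested by generalized least squares
#' with that covariance held fixed. Missing dosages are mean-imputed per
#' SNP after QC; monomorphic SNPs are flagged and excluded from the
#' p-value set. The test statistic is t-distributed with n - 2 degrees
#' of freedom (residual variance re-estimated per SNP), which reduces
#' exactly to the per-SNP ordinary least-squares t-test when K is the
#' identity.
#'
#' @param y Named phenotype vector (typically sire EBVs with
#'   reliabilities above a chosen floor).
#' @param gm A [GenotypeMatrix-class] with rows matching `y`.
#' @param K Kinship matrix from [ibsKinship()]; computed from `gm` when
#'   NULL.
#' @param covariates Optional fixed covariates (e.g. birth year).
#' @param trait Label stored on the result.
#' @return A [GwasResult-class].
#' @export
gwasScan <- function(y, gm, K = NULL, covariates = NULL, trait = "trait") {
  D <- dosages(gm)
  stopifnot(length(y) == nrow(D))
  if (is.null(K)) K <- ibsKinship(gm)
  null <- pseudoHeritability(y, K, covariates = covariates)
  sg <- null$varG; se <- null$varE
  eg <- eigen(symmetrize(as.matrix(K)), symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  w <- 1 / (sg * d + se)
  yt <- crossprod(U, y)
  X <- cbind(rep(1, length(y)), covariates)
  Xt <- crossprod(U, X)
  maf <- snpMaf(gm)
  callRate <- snpCallRate(gm)
  mono <- maf <= 0 | is.na(maf)
  ## mean-impute, then rotate all SNPs at once
  mu <- colMeans(D, na.rm = TRUE)
  Dimp <- D
  naIdx <- which(is.na(Dimp), arr.ind = TRUE)
  if (nrow(naIdx)) Dimp[naIdx] <- mu[naIdx[, 2L]]
  Gt <- crossprod(U, Dimp)
  ## GLS with fixed weights: partitioned normal equations per SNP
  A <- crossprod(Xt, w * Xt)
  Ainv <- solve(A)
  Xwy <- crossprod(Xt, w * yt)
  u <- Ainv %*% Xwy
  yWy <- sum(w * yt^2)
  baseRss <- yWy - sum(Xwy * u)
  Bx <- crossprod(Xt, w * Gt)                     # p x m
  cj <- colSums(w * Gt * Gt)
  gWy <- as.numeric(crossprod(Gt, w * yt))
  qj <- cj - colSums(Bx * (Ainv %*% Bx))
  mj <- gWy - as.numeric(crossprod(Bx, u))
  dfree <- length(y) - ncol(X) - 1L
  effect <- mj / qj
  rss <- baseRss - effect * mj
  sigma2 <- pmax(rss, 0) / dfree
  seB <- sqrt(sigma2 / qj)
  tstat <- effect / seB
  pval <- 2 * pt(-abs(tstat), df = dfree)
  tab <- data.frame(snp = snpMap(gm)$snp, chr = snpMap(gm)$chr,
                    pos = snpMap(gm)$pos, effect = effect, se = seB,
                    p = pval, maf = unname(maf),
                    callRate = unname(callRate),
                    monomorphic = unname(mono), stringsAsFactors = FALSE)
  tab$effect[mono] <- NA_real_
  tab$se[mono] <- NA_real_
  tab$p[mono] <- NA_real_
  new("GwasResult", table = tab, n = length(y), h2 = null$h2, trait = trait)
}

#' Bonferroni-significant SNP set
#'
#' Retains SNPs with p below alpha divided by the number of tested
#' (non-monomorphic) SNPs. The threshold is attached as an attribute;
#' the set is monotone in alpha.
#'
#' @param result A [GwasResult-class].
#' @param alpha Experiment-wise significance level (default 0.05).
#' @return data.frame of significant SNPs with attribute `"threshold"`.
#' @export
bonferroni <- function(result, alpha = 0.05) {
  tab <- gwasTable(result)
  tested <- tab[!tab$monomorphic & !is.na(tab$p), , drop = FALSE]
  thr <- alpha / max(1L, nrow(tested))
  out <- tested[tested$p <= thr, , drop = FALSE]
  attr(out, "threshold") <- thr
  attr(out, "m") <- nrow(tested)
  out
}

#' Compare marker effects between two traits
#'
#' Restricts both scans to shared SNPs with MAF above `mafMin`
#' (optionally the `topK` lowest-p SNPs of the first scan) and
#' regresses the effects of scan `a` on those of scan `b`, reporting
#' the coefficient of determination and the slope. A strong overall
#' genetic correlation need not be visible at the single-marker level.
#'
#' @param a,b Two [GwasResult-class] objects over a shared SNP panel.
#' @param mafMin MAF floor (default 0.10).
#' @param topK Optional: keep only the topK SNPs of `a` by p-value.
#' @return List with `r2`, `slope`, `n` and the paired effects table.
#' @export
crossTraitEffects <- function(a, b, mafMin = 0.10, topK = NULL) {
  ta <- gwasTable(a); tb <- gwasTable(b)
  ta <- ta[!ta$monomorphic & ta$maf > mafMin, ]
  tb <- tb[!tb$monomorphic & tb$maf > mafMin, ]
  mg <- merge(ta[, c("snp", "effect", "p")],
              tb[, c("snp", "effect")], by = "snp",
              suffixes = c("A", "B"))
  if (!is.null(topK)) mg <- mg[order(mg$p), ][seq_len(min(topK, nrow(mg))), ]
  if (nrow(mg) < 3L) stop("fewer than three shared SNPs after filtering")
  fit <- lm(effectA ~ effectB, data = mg)
  ## summary warns on an exact fit (e.g. a scan compared with itself)
  list(r2 = suppressWarnings(summary(fit))$r.squared,
       slope = unname(coef(fit)[2L]),
       n = nrow(mg), effects = mg)
}

## ---- PLINK-style text interchange -------------------------------------

#' Read and write PLINK-style text genotypes
#'
#' Minimal .ped/.map text interchange: the .map file has columns
#' chromosome, snp id, genetic distance, position; the .ped file has
#' family/individual/parents/sex/phenotype columns followed by two
#' allele letters (A/B, 0 for missing) per SNP. Dosage counts B
#' alleles.
#'
#' @param prefix Path prefix; `<prefix>.ped` and `<prefix>.map` are
#'   used.
#' @return [readPlink()] returns a [GenotypeMatrix-class].
#' @export
readPlink <- function(prefix) {
  map <- read.table(paste0(prefix, ".map"), header = FALSE,
                    col.names = c("chr", "snp", "cm", "pos"),
                    stringsAsFactors = FALSE)
  ped <- read.table(paste0(prefix, ".ped"), header = FALSE,
                    stringsAsFactors = FALSE)
  m <- nrow(map)
  if (ncol(ped) != 6L + 2L * m)
    stop("ped file does not match map: expected ", 6L + 2L * m, " columns")
  ids <- as.character(ped[[2L]])
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  a1 <- al[, seq(1L, 2L * m, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * m, by = 2L), drop = FALSE]
  miss <- a1 == "0" | a2 == "0"
  D <- (a1 == "B") + (a2 == "B")
  D[miss] <- NA
  storage.mode(D) <- "double"
  rownames(D) <- ids
  genotypeMatrix(D, map = data.frame(snp = map$snp, chr = map$chr,
                                     pos = map$pos,
                                     stringsAsFactors = FALSE))
}

#' @rdname readPlink
#' @param gm A [GenotypeMatrix-class] to write.
#' @export
writePlink <- function(gm, prefix) {
  map <- snpMap(gm)
  write.table(data.frame(map$chr, map$snp, 0, map$pos),
              paste0(prefix, ".map"), row.names = FALSE,
              col.names = FALSE, quote = FALSE, sep = "\t")
  D <- dosages(gm)
  n <- nrow(D); m <- ncol(D)
  a1 <- matrix("A", n, m); a2 <- matrix("A", n, m)
  a1[D >= 1] <- "B"
  a2[D == 2] <- "B"
  a1[is.na(D)] <- "0"; a2[is.na(D)] <- "0"
  geno <- matrix("", n, 2L * m)
  geno[, seq(1L, 2L * m, by = 2L)] <- a1
  geno[, seq(2L, 2L * m, by = 2L)] <- a2
  ids <- rownames(D) %||% paste0("ind", seq_len(n))
  out <- cbind("FAM", ids, "0", "0", "0", "-9", geno)
  write.table(out, paste0(prefix, ".ped"), row.names = FALSE,
              col.names = FALSE, quote = FALSE, sep = " ")
  invisible(prefix)
}
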