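# Mixed-model association machinery: QC, IBS kinship, genomic REML and
# the two-stage scan, checked against enumeration, OLS and simulated
# truth.

test_that("call-rate filtering matches brute-force enumeration", {
  withr::with_seed(61, {
    n <- 50; m <- 1000
    D <- matrix(rbinom(n * m, 2, 0.3), n, m)
    missRate <- runif(m, 0, 0.25)
    for (j in seq_len(m)) D[runif(n) < missRate[j], j] <- NA
    gm <- genotypeMatrix(D)
    kept <- suppressMessages(qcFilter(gm, 0.90))
    bruteKeep <- sum(colMeans(!is.na(D)) > 0.90)
    expect_identical(nSnps(kept), bruteKeep)
    ## no missingness: everything retained
    gmFull <- genotypeMatrix(matrix(rbinom(200, 2, 0.4), 10, 20))
    expect_identical(nSnps(suppressMessages(qcFilter(gmFull))), 20L)
    ## a single SNP at call rate 0.85 is removed at threshold 0.90
    D1 <- matrix(rbinom(40, 2, 0.5), 20, 2)
    D1[1:3, 1] <- NA                      # call rate 0.85
    expect_identical(snpMap(suppressMessages(qcFilter(genotypeMatrix(D1))))$snp,
                     "snp2")
  })
})

test_that("IBS kinship has the correct fixed points and pedigree ordering", {
  D <- rbind(a = c(0, 1, 2, 1), b = c(0, 1, 2, 1), c = c(2, 1, 0, 1))
  K <- ibsKinship(genotypeMatrix(D))
  expect_equal(K["a", "b"], 1)
  expect_equal(unname(diag(K)), rep(1, 3))
  opp <- rbind(x = c(0, 0, 2, 2), y = c(2, 2, 0, 0))
  expect_equal(ibsKinship(genotypeMatrix(opp))["x", "y"], 0)
  ## gene-dropped parent-offspring pairs score higher than unrelated pairs
  nFam <- 200L
  sires <- sprintf("s%03d", 1:nFam); kids <- sprintf("k%03d", 1:nFam)
  ped <- pedigree(id = c(sires, kids), sire = c(rep(NA, nFam), sires),
                  dam = NA, sex = c(rep("M", nFam), rep("F", nFam)))
  cfg <- simConfig(traits = c("protein", "cs"), nFounders = 10L,
                   nSnps = 2000L, nCausal = 0L, seed = 62)
  gm <- simulateGenotypes(ped, cfg)
  K2 <- ibsKinship(gm)
  po <- mean(K2[cbind(sires, kids)])
  unrel <- mean(K2[sires, sires][upper.tri(diag(nFam))])
  expect_gt(po, unrel)
})

test_that("pseudo-heritability recovers the simulated genetic fraction", {
  ped <- familyPedigree(60L, 5L, 2L)
  cfg <- simConfig(traits = c("protein", "cs"), nFounders = 10L,
                   nSnps = 600L, nCausal = 0L, seed = 63)
  gm <- simulateGenotypes(ped, cfg)
  K <- ibsKinship(gm)
  eg <- eigen(K, symmetric = TRUE)
  L <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  n <- nrow(K)
  h2s <- sapply(1:5, function(s) {
    withr::with_seed(70 + s, {
      y <- sqrt(0.6) * drop(L %*% rnorm(n)) + rnorm(n, 0, sqrt(0.4))
      pseudoHeritability(y, K)$h2
    })
  })
  expect_lt(abs(mean(h2s) - 0.6), 0.12)
  ## permuted labels destroy the genetic signal
  withr::with_seed(80, {
    y <- sqrt(0.6) * drop(L %*% rnorm(n)) + rnorm(n, 0, sqrt(0.4))
    permH2 <- sapply(1:3, function(i) pseudoHeritability(sample(y), K)$h2)
    expect_lt(mean(permH2), 0.1)
    ## no-noise limit: the estimate goes to one
    yPure <- drop(L %*% rnorm(n))
    expect_gt(pseudoHeritability(yPure, K)$h2, 0.98)
  })
})

test_that("the scan reduces exactly to per-SNP OLS when K is the identity", {
  withr::with_seed(64, {
    n <- 120; m <- 150
    D <- matrix(rbinom(n * m, 2, 0.35), n, m)
    gm <- genotypeMatrix(D)
    y <- rnorm(n) + 0.4 * D[, 7]
    res <- gwasScan(y, gm, K = diag(n))
    tab <- gwasTable(res)
    ols <- vapply(seq_len(m), function(j) {
      cf <- summary(lm(y ~ D[, j]))$coefficients
      c(cf[2, 1], cf[2, 2], cf[2, 4])
    }, numeric(3))
    expect_lt(max(abs(tab$effect - ols[1, ])), 1e-8)
    expect_lt(max(abs(tab$se - ols[2, ])), 1e-8)
    expect_lt(max(abs(tab$p - ols[3, ])), 1e-8)
  })
})

test_that("a causal SNP explaining 5% of variance is detected", {
  ## power check at Bonferroni stringency
  hits <- sapply(1:5, function(r) {
    withr::with_seed(500 + r, {
      n <- 1000; m <- 2000
      p <- runif(m, 0.1, 0.5)
      D <- sapply(p, function(pp) rbinom(n, 2, pp))
      causal <- 17L
      g <- scale(D[, causal])
      y <- sqrt(0.05) * g + rnorm(n, 0, sqrt(0.95))
      res <- gwasScan(drop(y), genotypeMatrix(D), K = diag(n))
      sig <- bonferroni(res)
      causal %in% match(sig$snp, gwasTable(res)$snp)
    })
  })
  expect_gte(sum(hits), 4L)
})

test_that("monomorphic SNPs are flagged and excluded from the p-value set", {
  withr::with_seed(65, {
    D <- matrix(rbinom(200, 2, 0.4), 20)
    D[, 3] <- 2
    res <- gwasScan(rnorm(20), genotypeMatrix(D), K = diag(20))
    tab <- gwasTable(res)
    expect_true(tab$monomorphic[3])
    expect_true(is.na(tab$p[3]))
    expect_false(any(bonferroni(res)$snp == tab$snp[3]))
  })
})

test_that("the Bonferroni set uses the tested-SNP count and is monotone", {
  withr::with_seed(66, {
    D <- matrix(rbinom(3000, 2, 0.4), 30)
    res <- gwasScan(rnorm(30), genotypeMatrix(D), K = diag(30))
    b05 <- bonferroni(res, 0.05)
    expect_equal(attr(b05, "threshold"), 0.05 / attr(b05, "m"))
    b20 <- bonferroni(res, 0.20)
    expect_true(all(b05$snp %in% b20$snp))
    ## threshold for the national marker panel size
    expect_equal(0.05 / 40498, 1.23e-6, tolerance = 0.01)
    allOne <- res
    allOne@table$p <- 1
    expect_identical(nrow(bonferroni(allOne)), 0L)
  })
})

test_that("cross-trait marker-effect comparison behaves at its fixed points", {
  withr::with_seed(67, {
    n <- 300; m <- 2000
    p <- runif(m, 0.05, 0.5)
    D <- sapply(p, function(pp) rbinom(n, 2, pp))
    gm <- genotypeMatrix(D)
    yA <- rnorm(n); yB <- rnorm(n)     # independent traits
    a <- gwasScan(yA, gm, K = diag(n), trait = "A")
    b <- gwasScan(yB, gm, K = diag(n), trait = "B")
    self <- crossTraitEffects(a, a)
    expect_equal(self$r2, 1)
    expect_equal(self$slope, 1)
    indep <- crossTraitEffects(a, b)
    expect_lt(indep$r2, 0.01)
    topTen <- crossTraitEffects(a, b, topK = 10L)
    expect_identical(topTen$n, 10L)
  })
  ## the MAF filter keeps exactly the bins above the floor
  withr::with_seed(68, {
    freqs <- rep(c(0.05, 0.15, 0.25), each = 30)
    n2 <- 4000
    D2 <- sapply(freqs, function(pp) rbinom(n2, 2, pp))
    gm2 <- genotypeMatrix(D2)
    y2 <- rnorm(n2)
    s1 <- gwasScan(y2, gm2, K = diag(n2))
    s2 <- gwasScan(rnorm(n2), gm2, K = diag(n2))
    ct <- crossTraitEffects(s1, s2, mafMin = 0.10)
    maf <- snpMaf(gm2)
    expect_identical(ct$n, sum(maf > 0.10))
    ## realized frequencies stay near their bins, so only the upper two
    ## bins survive
    expect_true(all(match(ct$effects$snp, snpMap(gm2)$snp) > 30))
  })
})

test_that("PLINK-style text genotypes round-trip", {
  withr::with_seed(69, {
    D <- matrix(rbinom(120, 2, 0.4), 10)
    D[2, 5] <- NA
    rownames(D) <- paste0("bull", 1:10)
    gm <- genotypeMatrix(D)
    pre <- file.path(tempdir(), "geno-rt")
    writePlink(gm, pre)
    back <- readPlink(pre)
    expect_equal(unname(dosages(back)), unname(dosages(gm)))
    expect_identical(rownames(dosages(back)), rownames(D))
    expect_identical(snpMap(back)$snp, snpMap(gm)$snp)
  })
})
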