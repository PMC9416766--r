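twoTraitCfg <- function(...) simConfig(traits = c("protein", "cs"), ...)

test_that("pedigree generator respects the structural contract", {
  cfg0 <- twoTraitCfg(nFounders = 10L, nGenerations = 0L, seed = 1)
  ped0 <- simulatePedigree(cfg0)
  expect_identical(length(ped0@id), 10L)
  expect_true(all(is.na(ped0@sire)) && all(is.na(ped0@dam)))

  cfg <- twoTraitCfg(nFounders = 20L, nGenerations = 3L,
                     progenyPerDam = 2L, missingParentRate = 0, seed = 2)
  ped <- simulatePedigree(cfg)
  df <- as.data.frame(ped)
  founder <- is.na(df$sire) & is.na(df$dam)
  expect_identical(sum(founder), 20L)   # no missingness: only true founders
  expect_true(all(!is.na(df$sire[!founder]) & !is.na(df$dam[!founder])))
  ## identical pedigree on re-run with the same seed (bit-identical file)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writePedigreeCsv(simulatePedigree(cfg), f1)
  writePedigreeCsv(simulatePedigree(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(simConfig(nFounders = 0), "positive")
})

test_that("gene-dropped breeding values reproduce the genetic covariance", {
  ## zero genetic variance -> exactly zero everywhere
  ped0 <- simulatePedigree(twoTraitCfg(nFounders = 50L, nGenerations = 1L,
                                       seed = 3))
  z <- simulateBreedingValues(ped0, matrix(0, 2, 2), seed = 3)
  expect_true(all(z$breedingValues == 0))

  ## founder sampling variance: single trait, unrelated animals
  cfg <- twoTraitCfg(nFounders = 10000L, nGenerations = 0L, seed = 4)
  ped <- simulatePedigree(cfg)
  tv <- simulateBreedingValues(ped, matrix(100, dimnames = list("t", "t")),
                               seed = 4)
  expect_lt(abs(var(tv$breedingValues[, 1]) - 100), 5)

  ## 2-trait founder covariance converges to G elementwise
  tv2 <- simulateBreedingValues(ped, genCov(ilTraitCovariances())[c("protein", "cs"),
                                                                  c("protein", "cs")],
                                seed = 5)
  Shat <- cov(tv2$breedingValues)
  expect_lt(abs(Shat["protein", "protein"] / 752.4 - 1), 0.06)
  expect_lt(abs(Shat["cs", "cs"] / 62.1 - 1), 0.06)
  expect_lt(abs(Shat["protein", "cs"] / -82.3 - 1), 0.15)
})

test_that("full-sib pairs have breeding-value correlation one half", {
  nFam <- 5000L
  sires <- sprintf("s%04d", 1:nFam)
  dams <- sprintf("d%04d", 1:nFam)
  k1 <- sprintf("a%04d", 1:nFam)
  k2 <- sprintf("b%04d", 1:nFam)
  ped <- pedigree(id = c(sires, dams, k1, k2),
                  sire = c(rep(NA, 2 * nFam), sires, sires),
                  dam = c(rep(NA, 2 * nFam), dams, dams),
                  sex = c(rep("M", nFam), rep("F", nFam),
                          rep("F", 2 * nFam)))
  tv <- simulateBreedingValues(ped, matrix(50, dimnames = list("t", "t")),
                               seed = 6)
  u <- tv$breedingValues[, 1]
  expect_lt(abs(cor(u[k1], u[k2]) - 0.5), 0.03)
})

test_that("phenotypes decompose into their effect layers", {
  tr <- c("protein", "cs")
  zeroE <- traitCovariances(genCov(ilTraitCovariances())[tr, tr],
                            matrix(0, 2, 2, dimnames = list(tr, tr)))
  cfg <- simConfig(covariances = zeroE, nFounders = 60L, nGenerations = 1L,
                   hysSd = c(0, 0),
                   parityEffects = matrix(0, 3, 2,
                                          dimnames = list(NULL, tr)),
                   seed = 7)
  ped <- simulatePedigree(cfg)
  tv <- simulateBreedingValues(ped, cfg@G, seed = 7)
  ph <- simulatePhenotypes(ped, tv, cfg)
  idx <- cbind(ph$animal, ph$trait)
  expect_equal(ph$value, unname(tv$breedingValues[idx]), tolerance = 1e-12)

  ## monotone missingness across parities is forced by sequential culling
  cfg2 <- twoTraitCfg(nFounders = 300L, nGenerations = 1L, seed = 8)
  ped2 <- simulatePedigree(cfg2)
  tv2 <- simulateBreedingValues(ped2, cfg2@G, seed = 8)
  ph2 <- simulatePhenotypes(ped2, tv2, cfg2)
  counts <- table(ph2$parity[ph2$trait == "protein"])
  expect_true(all(diff(as.numeric(counts)) <= 0))
  pro <- ph2[ph2$trait == "protein", ]
  animalsByParity <- split(pro$animal, pro$parity)
  expect_true(all(animalsByParity[[3]] %in% animalsByParity[[2]]))
  expect_true(all(animalsByParity[[2]] %in% animalsByParity[[1]]))
})

test_that("realized first-parity phenotypic variance matches G + E", {
  cfg <- twoTraitCfg(nFounders = 5000L, nGenerations = 0L, hysSd = c(0, 0),
                     seed = 9)
  ped <- simulatePedigree(cfg)
  tv <- simulateBreedingValues(ped, cfg@G, seed = 9)
  ph <- simulatePhenotypes(ped, tv, cfg)
  v <- var(ph$value[ph$trait == "protein" & ph$parity == 1])
  expect_lt(abs(v / (752.4 + 911.2) - 1), 0.10)
})

test_that("insemination sequences follow the conception process", {
  tr <- c("protein", "cs")
  Ez <- matrix(diag(c(911, 1101)), 2, 2, dimnames = list(tr, tr))
  Gz <- matrix(0, 2, 2, dimnames = list(tr, tr))
  base <- function(p, ...) {
    cfg <- simConfig(covariances = traitCovariances(Gz, Ez),
                     nFounders = 400L, nGenerations = 0L,
                     baselineConception = p, serviceCullRate = 0,
                     herdFertilitySd = 0, maxServices = 5L,
                     cullHazard = c(0, 0, 0), seed = 10, ...)
    ped <- simulatePedigree(cfg)
    tv <- simulateBreedingValues(ped, cfg@G, seed = 10)
    list(cfg = cfg, ped = ped,
         ins = simulateInseminations(ped, tv, cfg))
  }
  ## certain conception: one service each, CS = 100
  r1 <- base(1)
  cs1 <- conceptionStatus(r1$ins, herds = r1$ped)
  expect_true(all(cs1$services == 1L))
  expect_true(all(cs1$cs == 100))
  ## impossible conception: every sequence censored at maxServices
  r0 <- base(0)
  expect_false(any(r0$ins$outcome == "conceived"))
  maxServ <- tapply(r0$ins$service, paste(r0$ins$animal, r0$ins$parity), max)
  expect_true(all(maxServ == 5L))
  ## with no conception anywhere the trait is undefined
  expect_error(suppressMessages(conceptionStatus(r0$ins)), "undefined")
})

test_that("mean services among conceiving cows matches the enumeration oracle", {
  tr <- c("protein", "cs")
  zeroG <- traitCovariances(matrix(0, 2, 2, dimnames = list(tr, tr)),
                            matrix(diag(c(911, 1101)), 2, 2,
                                   dimnames = list(tr, tr)))
  cfg <- simConfig(covariances = zeroG, nFounders = 20000L,
                   nGenerations = 0L, baselineConception = 0.5,
                   serviceCullRate = 0, herdFertilitySd = 0,
                   maxServices = 5L, cullHazard = c(0, 1, 1), seed = 11)
  ped <- simulatePedigree(cfg)
  tv <- simulateBreedingValues(ped, cfg@G, seed = 11)
  ins <- simulateInseminations(ped, tv, cfg)
  cs <- conceptionStatus(ins, herds = ped)
  ## brute-force enumeration of the truncated outcome tree
  k <- 1:5; p <- 0.5
  probs <- p * (1 - p)^(k - 1)
  oracle <- sum(k * probs) / sum(probs)
  obs <- mean(cs$services[cs$conceived])
  expect_lt(abs(obs / oracle - 1), 0.02)
})

test_that("genotype gene dropping matches binomial and kinship expectations", {
  ## dosage variance 2pq at MAF 0.3
  cfg <- twoTraitCfg(nFounders = 10000L, nGenerations = 0L, nSnps = 200L,
                     nCausal = 0L, mafRange = c(0.3, 0.3), seed = 12)
  ped <- simulatePedigree(cfg)
  gm <- simulateGenotypes(ped, cfg)
  v <- mean(apply(dosages(gm), 2L, var))
  expect_lt(abs(v / 0.42 - 1), 0.05)

  ## parent-offspring dosage correlation 0.5 at MAF 0.5
  nFam <- 5000L
  sires <- sprintf("s%04d", 1:nFam); kids <- sprintf("k%04d", 1:nFam)
  ped2 <- pedigree(id = c(sires, kids), sire = c(rep(NA, nFam), sires),
                   dam = NA, sex = c(rep("M", nFam), rep("F", nFam)))
  cfg2 <- twoTraitCfg(nFounders = 10L, nSnps = 8L, nCausal = 0L,
                      mafRange = c(0.5, 0.5), seed = 13)
  gm2 <- simulateGenotypes(ped2, cfg2)
  D <- dosages(gm2)
  cors <- sapply(seq_len(ncol(D)), function(j) cor(D[sires, j], D[kids, j]))
  expect_lt(abs(mean(cors) - 0.5), 0.03)
})

test_that("without causal SNPs genotypes are independent of breeding values", {
  cfg <- twoTraitCfg(nFounders = 2000L, nGenerations = 0L, nSnps = 200L,
                     nCausal = 0L, seed = 14)
  ped <- simulatePedigree(cfg)
  gm <- simulateGenotypes(ped, cfg)
  tv <- simulateBreedingValues(ped, cfg@G, seed = 14)
  cors <- abs(cor(dosages(gm), tv$breedingValues[, "protein"]))
  expect_lt(max(cors), 0.1)
  expect_lt(mean(cors), 0.03)
})

test_that("causal effects tie genotypes to the target genetic covariance", {
  cfg <- twoTraitCfg(nFounders = 4000L, nGenerations = 0L, nSnps = 400L,
                     nCausal = 100L, seed = 15)
  ped <- simulatePedigree(cfg)
  gm <- simulateGenotypes(ped, cfg)
  gv <- gm@causal$geneticValues
  S <- cov(gv)
  ## covariance of genomic values approximates the 2x2 G block; the
  ## effect draw itself is random, so the bound is loose
  expect_lt(abs(S["protein", "protein"] / 752.4 - 1), 0.5)
  expect_equal(sign(S["protein", "cs"]), -1)
  expect_error(simConfig(nSnps = 10L, nCausal = 20L), "exceed")
})

test_that("every simulated table is bit-identical under a fixed seed", {
  cfg <- twoTraitCfg(nFounders = 60L, nGenerations = 2L, nSnps = 50L,
                     seed = 16)
  ped <- simulatePedigree(cfg)
  tv <- simulateBreedingValues(ped, cfg@G, seed = 16)
  expect_identical(simulatePhenotypes(ped, tv, cfg),
                   simulatePhenotypes(ped, tv, cfg))
  expect_identical(simulateInseminations(ped, tv, cfg),
                   simulateInseminations(ped, tv, cfg))
  expect_identical(dosages(simulateGenotypes(ped, cfg)),
                   dosages(simulateGenotypes(ped, cfg)))
})

test_that("realized half-sib heritability is consistent with G and E", {
  ## paternal half-sib ANOVA as a crude variance-decomposition oracle
  ped <- familyPedigree(100, 20, 1)   # 100 sires x 20 half-sib daughters
  cows <- animalIds(ped)[grepl("^C", animalIds(ped))]
  G <- genCov(ilTraitCovariances())["protein", "protein", drop = FALSE]
  E <- envCov(ilTraitCovariances())["protein", "protein", drop = FALSE]
  tv <- simulateBreedingValues(ped, G, seed = 17)
  y <- tv$breedingValues[cows, 1] +
    withr::with_seed(18, rnorm(length(cows), 0, sqrt(E[1, 1])))
  fam <- sub("^C(\\d+)_.*", "\\1", cows)
  m <- 20
  msb <- m * var(tapply(y, fam, mean))
  msw <- sum((y - ave(y, fam))^2) / (length(y) - 100)
  sf <- (msb - msw) / m
  h2hat <- 4 * sf / (sf + msw)
  expect_lt(abs(h2hat - 0.45), 0.12)
})
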