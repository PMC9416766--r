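singleTraitCov <- function(g, e) {
  traitCovariances(matrix(g, dimnames = list("t", "t")),
                   matrix(e, dimnames = list("t", "t")))
}

test_that("scalar mixed-model equations reduce to the shrinkage closed form", {
  ped <- pedigree(id = "x", sire = NA, dam = NA, sex = "F")
  ph <- data.frame(animal = "x", trait = "t", value = 5,
                   stringsAsFactors = FALSE)
  cv <- singleTraitCov(2, 3)
  sol <- solveMME(buildMME(ph, ped, cv, fixed = character(0)))
  expect_equal(unname(sol$ebv["x", "t"]), 5 * 2 / (2 + 3))
  ## no records at all: EBVs are zero
  empty <- ph[0, ]
  sol0 <- solveMME(buildMME(empty, ped, cv, fixed = character(0)))
  expect_equal(unname(sol0$ebv["x", "t"]), 0)
})

test_that("a related trio with two traits matches dense GLS/BLUP", {
  ped <- pedigree(id = c("s", "d", "x"), sire = c(NA, NA, "s"),
                  dam = c(NA, NA, "d"), sex = c("M", "F", "F"))
  tr <- c("t1", "t2")
  G <- matrix(c(4, 1, 1, 2), 2, dimnames = list(tr, tr))
  E <- matrix(c(5, -1, -1, 3), 2, dimnames = list(tr, tr))
  cv <- traitCovariances(G, E)
  ph <- data.frame(animal = rep(c("d", "x"), each = 2),
                   trait = rep(tr, 2), value = c(1.3, -0.4, 2.2, 0.9),
                   stringsAsFactors = FALSE)
  sol <- solveMME(buildMME(ph, ped, cv, fixed = character(0)))
  or <- denseBlupOracle(ph, ped, cv)
  expect_equal(sol$ebv, or$ebv, tolerance = 1e-10)
})

test_that("sparse MME equals dense GLS/BLUP on random multi-trait instances", {
  for (seed in 1:10) {
    inst <- randomBlupInstance(seed)
    mme <- buildMME(inst$ph, inst$ped, inst$cov, fixed = "hys")
    sol <- solveMME(mme)
    or <- denseBlupOracle(inst$ph, inst$ped, inst$cov, fixed = "hys")
    expect_lt(max(abs(sol$ebv - or$ebv)), 1e-6)
  }
})

test_that("direct and conjugate-gradient solvers agree; order is irrelevant", {
  inst <- randomBlupInstance(99, maxAnimals = 120L)
  mme <- buildMME(inst$ph, inst$ped, inst$cov, fixed = "hys")
  d <- solveMME(mme, method = "direct")
  cg <- solveMME(mme, method = "cg", tol = 1e-12)
  expect_lt(max(abs(d$solution - cg$solution)), 1e-6)
  ## permuting record order leaves solutions unchanged
  perm <- withr::with_seed(1, sample(nrow(inst$ph)))
  mme2 <- buildMME(inst$ph[perm, ], inst$ped, inst$cov, fixed = "hys")
  d2 <- solveMME(mme2)
  expect_lt(max(abs(d$ebv - d2$ebv)), 1e-8)
})

test_that("reliabilities equal the brute-force prediction-error variances", {
  inst <- randomBlupInstance(7, maxAnimals = 50L)
  mme <- buildMME(inst$ph, inst$ped, inst$cov, fixed = "hys")
  rel <- reliability(mme, inst$cov)
  or <- denseBlupOracle(inst$ph, inst$ped, inst$cov, fixed = "hys")
  g <- diag(genCov(inst$cov))
  relOracle <- 1 - sweep(or$pev, 2L, g, "/")
  relOracle <- pmin(pmax(relOracle, 0), 1 - 1e-12)
  expect_equal(rel, relOracle[rownames(rel), ], tolerance = 1e-6)
  ## an animal with no records and no informative relatives has r2 = 0
  ped <- pedigree(id = c("a", "b"), sire = NA, dam = NA, sex = c("F", "F"))
  cv <- singleTraitCov(2, 3)
  ph <- data.frame(animal = "a", trait = "t", value = 1,
                   stringsAsFactors = FALSE)
  mme2 <- buildMME(ph, ped, cv, fixed = character(0))
  r2 <- reliability(mme2, cv)
  expect_equal(unname(r2["b", "t"]), 0)
  ## near-infinite precision record: r2 -> 1
  cvLim <- singleTraitCov(2, 1e-10)
  r2lim <- reliability(buildMME(ph, ped, cvLim, fixed = character(0)), cvLim)
  expect_gt(unname(r2lim["a", "t"]), 1 - 1e-6)
})

test_that("rebasing is idempotent, shift-invariant and zero-mean", {
  withr::with_seed(11, {
    ebvM <- matrix(rnorm(30), 10, 3,
                   dimnames = list(paste0("a", 1:10), paste0("t", 1:3)))
    all10 <- rebase(ebvM, rownames(ebvM))
    expect_equal(unname(colMeans(all10)), rep(0, 3))
    once <- rebase(ebvM, paste0("a", 1:4))
    twice <- rebase(once, paste0("a", 1:4))
    expect_equal(unname(once), unname(twice))
    shifted <- rebase(ebvM + 7, paste0("a", 1:4))
    expect_equal(unname(shifted), unname(once))
    expect_error(rebase(ebvM, character(0)), "empty")
  })
})

test_that("parity combination is a normalized weighted sum", {
  ebvP <- matrix(c(10, 20, 30), 1, dimnames = list("a", NULL))
  expect_equal(unname(combineParities(ebvP, c(0.5, 0.3, 0.2))), 17)
  expect_equal(unname(combineParities(ebvP, c(1, 0, 0))), 10)
  same <- matrix(5, 4, 3)
  expect_equal(unname(combineParities(same, c(1, 1, 1))), rep(5, 4))
  expect_error(combineParities(ebvP, c(0.5, -0.1, 0.6)), "negative")
})

test_that("realized trends recover the slope of EBV on birth date", {
  birth <- as.Date("2000-06-30") + round(365.25 * (0:9))
  tab <- data.frame(animal = as.character(1:10), trait = "t",
                    ebv = 2.5 * herdtrend:::decimalYear(birth),
                    birth = birth, stringsAsFactors = FALSE)
  tr <- realizedTrends(tab)
  expect_equal(tr$slope, 2.5, tolerance = 1e-8)
  expect_lt(tr$se, 1e-6)
  flat <- tab; flat$ebv <- 4
  expect_equal(realizedTrends(flat)$slope, 0, tolerance = 1e-10)
  expect_error(realizedTrends(tab[1:2, ]), "three")
  ## noisy line: slope within 3 SE of truth
  withr::with_seed(12, {
    n <- 10000
    b <- sample(birth, n, replace = TRUE)
    noisy <- data.frame(animal = as.character(1:n), trait = "t",
                        ebv = 2.5 * herdtrend:::decimalYear(b) + rnorm(n),
                        birth = b, stringsAsFactors = FALSE)
    tn <- realizedTrends(noisy)
    expect_lt(abs(tn$slope - 2.5), 3 * tn$se)
  })
})

test_that("evaluation wrapper rebases to a birth-year cohort", {
  cfg <- simConfig(traits = c("protein", "cs"), nFounders = 40L,
                   nGenerations = 2L, missingParentRate = 0, seed = 21)
  ped <- simulatePedigree(cfg)
  tv <- simulateBreedingValues(ped, cfg@G, seed = 21)
  ph <- simulatePhenotypes(ped, tv, cfg)
  yr <- as.integer(format(ped@birth, "%Y"))
  baseYear <- as.integer(names(which.max(table(yr))))
  res <- blupEvaluate(ph, ped, traitCovariances(cfg@G, cfg@E),
                      baseCohort = baseYear)
  cohort <- animalIds(ped)[yr == baseYear]
  expect_equal(unname(colMeans(ebv(res)[cohort, ])), c(0, 0),
               tolerance = 1e-10)
})
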