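# The REML iterator is checked against closed forms and its own
# alternative update (EM vs average information), then against the
# generating parameters of simulated populations.

halfSibData <- function(sg, se, s = 40L, m = 12L, seed = 101) {
  ped <- familyPedigree(s, m, 1L)          # s sires x m half-sib daughters
  cows <- animalIds(ped)[grepl("^C", animalIds(ped))]
  G <- matrix(sg, dimnames = list("t", "t"))
  tv <- simulateBreedingValues(ped, G, seed = seed)
  y <- tv$breedingValues[cows, 1] +
    withr::with_seed(seed + 1L, rnorm(length(cows), 0, sqrt(se)))
  list(ped = ped, cows = cows, y = y, fam = sub("^C(\\d+)_.*", "\\1", cows),
       m = m, s = s,
       ph = data.frame(animal = cows, trait = "t", value = y,
                       stringsAsFactors = FALSE))
}

test_that("balanced half-sib REML equals the closed-form ANOVA estimator", {
  d <- halfSibData(30, 70)
  msb <- d$m * var(tapply(d$y, d$fam, mean))
  msw <- sum((d$y - ave(d$y, d$fam))^2) / (length(d$y) - d$s)
  sf <- (msb - msw) / d$m            # between-sire component
  anovaG <- 4 * sf                   # sigma_g under the animal model
  anovaE <- msw - 3 * sf
  fit <- remlFit(d$ph, d$ped, fixed = "mean", method = "ai", tol = 1e-12,
                 maxIter = 200L)
  expect_true(fit@converged)
  expect_lt(abs(genCov(covariances(fit))[1, 1] - anovaG), 1e-6)
  expect_lt(abs(envCov(covariances(fit))[1, 1] - anovaE), 1e-6)
})

test_that("zero genetic variance is recovered at the boundary", {
  d <- halfSibData(0, 100, s = 100L, m = 20L, seed = 55)
  fit <- remlFit(d$ph, d$ped, fixed = "mean", method = "em-then-ai",
                 tol = 1e-8, maxIter = 200L)
  cv <- covariances(fit)
  expect_lt(genCov(cv)[1, 1], 0.05 * envCov(cv)[1, 1])
})

test_that("EM iterations never decrease the restricted likelihood", {
  d <- halfSibData(30, 70, seed = 7)
  fit <- remlFit(d$ph, d$ped, fixed = "mean", method = "em", tol = 1e-9,
                 maxIter = 60L)
  expect_true(all(diff(fit@logLik) > -1e-8))
})

test_that("EM and AI converge to the same optimum", {
  ## well-conditioned 2-trait problem, moderate heritabilities
  tr <- c("x", "z")
  G <- matrix(c(40, 12, 12, 30), 2, dimnames = list(tr, tr))
  E <- matrix(c(60, -5, -5, 70), 2, dimnames = list(tr, tr))
  ped <- familyPedigree(40L, 8L, 2L)
  cows <- animalIds(ped)[ped@sex == "F"]
  tv <- simulateBreedingValues(ped, G, seed = 13)
  n <- length(cows)
  Y <- tv$breedingValues[cows, ] +
    withr::with_seed(14, matrix(rnorm(2 * n), n) %*% chol(E))
  ph <- data.frame(animal = rep(cows, 2),
                   trait = rep(tr, each = n), value = c(Y[, 1], Y[, 2]),
                   stringsAsFactors = FALSE)
  fitAI <- remlFit(ph, ped, fixed = "mean", method = "em-then-ai",
                   tol = 1e-10, maxIter = 200L)
  fitEM <- remlFit(ph, ped, fixed = "mean", method = "em", tol = 1e-9,
                   maxIter = 3000L)
  thAI <- c(genCov(covariances(fitAI)), envCov(covariances(fitAI)))
  thEM <- c(genCov(covariances(fitEM)), envCov(covariances(fitEM)))
  expect_lt(max(abs(thAI - thEM)) / mean(abs(thAI)), 1e-4)
  ## AI attaches standard errors from the inverse information matrix
  se <- covariances(fitAI)@se
  expect_false(is.null(se))
  expect_true(all(diag(se$G) > 0))
})

test_that("two-trait recovery reproduces national protein/fertility parameters", {
  ## trimmed-down version of the full recovery study (see the
  ## acceptance suite): 6 replicates at 1500 cows
  reps <- sapply(1:6, function(r) {
    ped <- familyPedigree(25L, 20L, 2L)
    cows <- animalIds(ped)[ped@sex == "F"]
    vc <- ilTraitCovariances()[c("protein", "cs")]
    tv <- simulateBreedingValues(ped, genCov(vc), seed = 200 + r)
    n <- length(cows)
    Y <- tv$breedingValues[cows, ] +
      withr::with_seed(300 + r, matrix(rnorm(2 * n), n) %*% chol(envCov(vc)))
    ph <- data.frame(animal = rep(cows, 2),
                     trait = rep(c("protein", "cs"), each = n),
                     value = c(Y[, 1], Y[, 2]), stringsAsFactors = FALSE)
    fit <- remlFit(ph, ped, fixed = "mean", method = "em-then-ai",
                   tol = 1e-6, maxIter = 100L, emWarmup = 5L)
    cv <- covariances(fit)
    c(heritability(cv, "protein"), heritability(cv, "cs"),
      geneticCorrelation(cv, "protein", "cs"))
  })
  m <- rowMeans(reps)
  expect_lt(abs(m[1] - 0.45), 0.08)
  expect_lt(abs(m[2] - 0.05), 0.05)
  expect_lt(abs(m[3] - (-0.38)), 0.25)
})

test_that("derived genetic parameters follow their defining formulas", {
  vc <- ilTraitCovariances()
  expect_equal(round(heritability(vc, "protein"), 2), 0.45)
  expect_equal(round(heritability(vc, "cs"), 2), 0.05)
  expect_equal(heritability(vc, "milk"),
               1104690.4 / (1104690.4 + 1072573.5))
  expect_equal(round(geneticCorrelation(vc, "protein", "cs"), 2), -0.38)
  expect_equal(round(geneticCorrelation(vc, "milk", "protein"), 2), 0.85)
  expect_equal(geneticCorrelation(vc, "cs", "cs"), 1)
  ## E_tt = 0 limit: heritability one
  one <- traitCovariances(matrix(3, dimnames = list("t", "t")),
                          matrix(0, dimnames = list("t", "t")))
  expect_equal(heritability(one, "t"), 1)
  zero <- traitCovariances(matrix(0, dimnames = list("t", "t")),
                           matrix(0, dimnames = list("t", "t")))
  expect_error(heritability(zero, "t"), "undefined")
  expect_error(geneticCorrelation(zero, "t", "t"), "undefined")
})

test_that("the parameter matrix uses the conventional reporting layout", {
  vc <- ilTraitCovariances()
  pm <- parameterMatrix(vc, below = "phenotypic")
  expect_equal(diag(pm), sapply(traitNames(vc), heritability, cov = vc))
  expect_equal(pm["milk", "protein"],
               geneticCorrelation(vc, "milk", "protein"))
  expect_equal(round(pm["protein", "milk"], 2), 0.90)
  pe <- parameterMatrix(vc, below = "environmental")
  expect_equal(pe["protein", "milk"],
               environmentalCorrelation(vc, "protein", "milk"))
  ## correlations stay in [-1, 1] even after flooring a non-PSD input
  expect_true(all(abs(pm[upper.tri(pm)]) <= 1))
})
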