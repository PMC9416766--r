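## Synthetic population generator: multi-generation pedigrees, gene-dropped
## breeding values, herd-year-season structured multi-parity phenotypes,
## per-cow insemination sequences and SNP genotypes. The defaults emulate
## the Israeli Holstein national data structure at desk scale, with trait
## (co)variances from the published first-parity national estimates.

#' Simulation configuration
#'
#' All knobs of the synthetic-population generator. Defaults are the
#' study conditions: the nine index traits with the published national
#' genetic/environmental covariances, herd-year-season effects
#' contributing 10 percent of the within-class phenotypic variance,
#' three parities with monotone attrition, and a per-service conception
#' probability around the national mean.
#'
#' @slot nFounders,nGenerations,damsPerSire,progenyPerDam,nHerds,yearsSpanned
#'   Population-structure counts.
#' @slot G,E Trait covariance matrices (identical labels).
#' @slot hysSd Per-trait SD of herd-year-season effects.
#' @slot parityEffects Parity x trait matrix of fixed shifts.
#' @slot maxServices Services before a fertility record is censored.
#' @slot missingParentRate Fraction of non-founders with unknown parent(s).
#' @slot cullHazard Per-parity culling probability.
#' @slot serviceCullRate Per-service probability a cow leaves mid-sequence.
#' @slot baselineConception Per-service conception probability of an
#'   average cow in an average herd.
#' @slot herdFertilitySd SD of the per-herd shift of the conception
#'   logit (herd-level fertility management differences).
#' @slot nSnps,nCausal,mafRange,genoMissingRate Genotype settings.
#' @slot seed Master seed; every operation draws from a named child
#'   stream so modules are independently reproducible.
#' @seealso [simConfig()]
#' @export
setClass("SimConfig",
  representation(nFounders = "integer", nGenerations = "integer",
                 damsPerSire = "integer", progenyPerDam = "integer",
                 nHerds = "integer", yearsSpanned = "numeric",
                 G = "matrix", E = "matrix", hysSd = "numeric",
                 parityEffects = "matrix", maxServices = "integer",
                 missingParentRate = "numeric", cullHazard = "numeric",
                 serviceCullRate = "numeric", baselineConception = "numeric",
                 herdFertilitySd = "numeric",
                 nSnps = "integer", nCausal = "integer",
                 mafRange = "numeric", genoMissingRate = "numeric",
                 seed = "integer"))

setValidity("SimConfig", function(object) {
  msgs <- character(0)
  if (object@nFounders < 1L) msgs <- c(msgs, "nFounders must be positive")
  if (object@nGenerations < 0L) msgs <- c(msgs, "nGenerations must be >= 0")
  for (sl in c("damsPerSire", "progenyPerDam", "nHerds", "maxServices"))
    if (slot(object, sl) < 1L) msgs <- c(msgs, paste(sl, "must be positive"))
  if (!identical(dimnames(object@G), dimnames(object@E)))
    msgs <- c(msgs, "G and E must share trait labels")
  if (!isPSD(object@G)) msgs <- c(msgs, "G must be symmetric PSD")
  if (!isPSD(object@E)) msgs <- c(msgs, "E must be symmetric PSD")
  for (sl in c("missingParentRate", "genoMissingRate", "serviceCullRate"))
    if (slot(object, sl) < 0 || slot(object, sl) > 1)
      msgs <- c(msgs, paste(sl, "must be in [0, 1]"))
  if (any(object@cullHazard < 0 | object@cullHazard > 1))
    msgs <- c(msgs, "cullHazard must be probabilities")
  if (object@baselineConception < 0 || object@baselineConception > 1)
    msgs <- c(msgs, "baselineConception must be in [0, 1]")
  if (object@herdFertilitySd < 0)
    msgs <- c(msgs, "herdFertilitySd must be non-negative")
  if (length(object@mafRange) != 2L || any(object@mafRange <= 0) ||
      any(object@mafRange > 0.5) || diff(object@mafRange) < 0)
    msgs <- c(msgs, "mafRange must be (low, high) in (0, 0.5]")
  if (object@nCausal > object@nSnps)
    msgs <- c(msgs, "nCausal cannot exceed nSnps")
  if (length(object@hysSd) != ncol(object@G))
    msgs <- c(msgs, "hysSd must have one entry per trait")
  if (ncol(object@parityEffects) != ncol(object@G))
    msgs <- c(msgs, "parityEffects must have one column per trait")
  if (length(object@cullHazard) != nrow(object@parityEffects))
    msgs <- c(msgs, "cullHazard needs one entry per parity")
  if (length(msgs)) msgs else TRUE
})

#' Build a simulation configuration
#'
#' See [SimConfig-class] for slot meanings. `hysSd` defaults to
#' `sqrt(0.1 * diag(G + E))` (management groups explain about a tenth of
#' phenotypic variance); `parityEffects` defaults to shifts of 0, 0.3 and
#' 0.4 phenotypic SD for parities 1-3, the typical maturity gain.
#'
#' @param covariances A [TraitCovariances-class]; defaults to the
#'   published nine-trait national estimates [ilTraitCovariances()].
#' @param traits Optional subset of traits to simulate.
#' @param nFounders,nGenerations,damsPerSire,progenyPerDam,nHerds,yearsSpanned
#'   Population structure.
#' @param hysSd,parityEffects,maxServices,missingParentRate,cullHazard,serviceCullRate,baselineConception
#'   See [SimConfig-class].
#' @param nSnps,nCausal,mafRange,genoMissingRate Genotype settings.
#' @param seed Master seed.
#' @return A validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(traits = c("protein", "cs"), nFounders = 40,
#'                  nGenerations = 2, seed = 7)
#' ped <- simulatePedigree(cfg)
#' @export
simConfig <- function(covariances = ilTraitCovariances(), traits = NULL,
                      nFounders = 200L, nGenerations = 3L, damsPerSire = 4L,
                      progenyPerDam = 3L, nHerds = 10L, yearsSpanned = 10,
                      hysSd = NULL, parityEffects = NULL, maxServices = 8L,
                      missingParentRate = 0.05,
                      cullHazard = c(0.25, 0.30, 0.35),
                      serviceCullRate = 0.02, baselineConception = 0.45,
                      herdFertilitySd = 0.15, nSnps = 1000L, nCausal = 50L,
                      mafRange = c(0.05, 0.5), genoMissingRate = 0,
                      seed = 1L) {
  if (!is.null(traits)) covariances <- covariances[traits]
  G <- genCov(covariances); E <- envCov(covariances)
  pSd <- sqrt(diag(G + E))
  if (is.null(hysSd)) hysSd <- sqrt(0.1) * pSd
  if (is.null(parityEffects)) {
    parityEffects <- outer(c(0, 0.3, 0.4), pSd)
    dimnames(parityEffects) <- list(NULL, colnames(G))
  }
  parityEffects <- as.matrix(parityEffects)
  new("SimConfig", nFounders = as.integer(nFounders),
      nGenerations = as.integer(nGenerations),
      damsPerSire = as.integer(damsPerSire),
      progenyPerDam = as.integer(progenyPerDam),
      nHerds = as.integer(nHerds), yearsSpanned = as.numeric(yearsSpanned),
      G = G, E = E, hysSd = as.numeric(hysSd),
      parityEffects = parityEffects, maxServices = as.integer(maxServices),
      missingParentRate = missingParentRate,
      cullHazard = as.numeric(cullHazard),
      serviceCullRate = serviceCullRate,
      baselineConception = baselineConception,
      herdFertilitySd = herdFertilitySd,
      nSnps = as.integer(nSnps), nCausal = as.integer(nCausal),
      mafRange = as.numeric(mafRange), genoMissingRate = genoMissingRate,
      seed = as.integer(seed))
}

#' Simulate a multi-generation pedigree
#'
#' Discrete generations: founders (half of each sex) followed by
#' `nGenerations` rounds of random mating in which each dam produces
#' `progenyPerDam` offspring and sires serve `damsPerSire` dams.
#' Offspring inherit the dam's herd; birth dates advance by
#' `yearsSpanned / nGenerations` per generation with within-cohort
#' jitter. A fraction `missingParentRate` of non-founders loses the
#' sire, the dam, or both.
#'
#' @param config A [SimConfig-class].
#' @param seed Override of `config@seed`.
#' @return A [Pedigree-class].
#' @export
simulatePedigree <- function(config, seed = config@seed) {
  stopifnot(is(config, "SimConfig"))
  if (config@nFounders < 1L) stop("need at least one founder")
  withSeed(childSeed(seed, "pedigree"), {
    nF <- config@nFounders
    genGap <- config@yearsSpanned / max(1L, config@nGenerations)
    id <- sprintf("A%06d", seq_len(nF))
    sex <- rep(c("M", "F"), length.out = nF)[sample.int(nF)]
    herd <- paste0("H", sample.int(config@nHerds, nF, replace = TRUE))
    birth <- as.Date("2000-01-01") +
      round(365.25 * runif(nF, 0, min(1, genGap)))
    sire <- rep(NA_character_, nF)
    dam <- rep(NA_character_, nF)
    nextId <- nF + 1L
    prev <- data.frame(id = id, sex = sex, herd = herd,
                       stringsAsFactors = FALSE)
    for (g in seq_len(config@nGenerations)) {
      sires <- prev$id[prev$sex == "M"]
      dams <- prev$id[prev$sex == "F"]
      if (!length(sires) || !length(dams))
        stop("generation ", g, " has no available sires or dams")
      nS <- max(1L, ceiling(length(dams) / config@damsPerSire))
      useSires <- sample(sires, min(nS, length(sires)))
      damSire <- rep(useSires, length.out = length(dams))[sample.int(length(dams))]
      nOff <- length(dams) * config@progenyPerDam
      offId <- sprintf("A%06d", seq.int(nextId, length.out = nOff))
      nextId <- nextId + nOff
      offDam <- rep(dams, each = config@progenyPerDam)
      offSire <- rep(damSire, each = config@progenyPerDam)
      offSex <- sample(c("M", "F"), nOff, replace = TRUE)
      offHerd <- prev$herd[match(offDam, prev$id)]
      offBirth <- as.Date("2000-01-01") +
        round(365.25 * (g * genGap + runif(nOff, 0, min(1, genGap))))
      ## unknown-parent thinning
      lose <- runif(nOff) < config@missingParentRate
      which <- sample(c("sire", "dam", "both"), nOff, replace = TRUE,
                      prob = c(0.4, 0.4, 0.2))
      offSire[lose & which %in% c("sire", "both")] <- NA
      offDam[lose & which %in% c("dam", "both")] <- NA
      id <- c(id, offId); sire <- c(sire, offSire); dam <- c(dam, offDam)
      sex <- c(sex, offSex); herd <- c(herd, offHerd)
      birth <- c(birth, offBirth)
      prev <- data.frame(id = offId, sex = offSex, herd = offHerd,
                         stringsAsFactors = FALSE)
    }
    pedigree(id = id, sire = sire, dam = dam, sex = sex, birth = birth,
             herd = herd)
  })
}

# Symmetric square root used by the gene dropper; tolerates PSD-singular
# G (e.g. a zero matrix) and rejects indefinite input.
.matSqrt <- function(G) {
  eg <- eigen(symmetrize(G), symmetric = TRUE)
  tol <- 1e-8 * max(1, sum(abs(diag(G))))
  if (min(eg$values) < -tol) stop("covariance matrix is not PSD")
  vals <- sqrt(pmax(eg$values, 0))
  eg$vectors %*% (vals * t(eg$vectors))
}

#' Gene-drop true breeding values through a pedigree
#'
#' Founders are drawn with covariance G; each non-founder receives the
#' mid-parent mean plus a Mendelian-sampling deviation with covariance
#' (1/2 - (F_s + F_d)/4) G, where F is the parental inbreeding. An
#' unknown parent contributes a phantom founder draw, so animals with
#' unknown ancestry still have full genetic variance.
#'
#' @param ped A [Pedigree-class].
#' @param G Genetic covariance matrix (PSD).
#' @param seed Integer seed.
#' @return List with `breedingValues` (animal x trait matrix, pedigree
#'   order) -- the ground truth for parameter-recovery tests.
#' @export
simulateBreedingValues <- function(ped, G, seed = 1L) {
  stopifnot(is(ped, "Pedigree"))
  G <- as.matrix(G)
  S <- .matSqrt(G)
  J <- ncol(G)
  p <- .parentIdx(ped)
  F <- computeInbreeding(ped)
  n <- length(ped@id)
  withSeed(childSeed(seed, "breeding-values"), {
    U <- matrix(0, n, J, dimnames = list(ped@id, colnames(G)))
    for (i in seq_len(n)) {
      s <- p$s[i]; d <- p$d[i]
      if (s == 0L && d == 0L) {
        U[i, ] <- S %*% rnorm(J)
        next
      }
      us <- if (s > 0L) U[s, ] else drop(S %*% rnorm(J))  # phantom sire
      ud <- if (d > 0L) U[d, ] else drop(S %*% rnorm(J))  # phantom dam
      fs <- if (s > 0L) F[s] else 0
      fd <- if (d > 0L) F[d] else 0
      mend <- sqrt(0.5 - 0.25 * (fs + fd)) * drop(S %*% rnorm(J))
      U[i, ] <- 0.5 * (us + ud) + mend
    }
    list(breedingValues = U)
  })
}

# Shared parity profile: per-cow last parity (sequential culling) and
# freshening dates. Phenotype and insemination simulation call this with
# the same child seed so their culling patterns agree.
.parityProfile <- function(ped, config, seed) {
  nP <- nrow(config@parityEffects)
  cows <- which(ped@sex == "F")
  withSeed(childSeed(seed, "cull"), {
    nC <- length(cows)
    cull <- matrix(runif(nC * nP) < rep(config@cullHazard, each = nC),
                   nC, nP)
    lastParity <- apply(cull, 1L, function(z) {
      w <- which(z); if (length(w)) w[1L] else nP
    })
    jit <- matrix(runif(nC * nP, -60, 60), nC, nP)
    fresh <- matrix(NA_real_, nC, nP)  # Date stored as days since epoch
    for (p in seq_len(nP))
      fresh[, p] <- as.numeric(ped@birth[cows]) +
        round(730 + 405 * (p - 1) + jit[, p])
    list(cows = cows, lastParity = lastParity, fresh = fresh)
  })
}

#' Simulate multi-parity phenotypes
#'
#' Each record is parity effect + herd-year-season effect + breeding
#' value + residual, with residual covariance E across traits and
#' independent residuals across parities. Cows are culled sequentially,
#' so a later parity is present only if all earlier parities are
#' present. Herd-year-season classes follow the freshening date (April
#' and October season boundaries).
#'
#' @param ped A [Pedigree-class]; every cow must have a herd.
#' @param trueValues Output of [simulateBreedingValues()].
#' @param config A [SimConfig-class].
#' @param seed Override of `config@seed`.
#' @return Long data.frame(animal, parity, trait, value, hys, fresh).
#'   The drawn herd-year-season effects are attached as attribute
#'   `"hysEffects"`.
#' @export
simulatePhenotypes <- function(ped, trueValues, config, seed = config@seed) {
  stopifnot(is(ped, "Pedigree"))
  traits <- colnames(config@G)
  U <- trueValues$breedingValues[, traits, drop = FALSE]
  prof <- .parityProfile(ped, config, seed)
  cows <- prof$cows
  if (any(is.na(ped@herd[cows])))
    stop("every phenotyped cow needs a herd assignment")
  nP <- nrow(config@parityEffects)
  J <- length(traits)
  Es <- .matSqrt(config@E)
  rows <- list()
  for (p in seq_len(nP)) {
    keep <- prof$lastParity >= p
    if (!any(keep)) next
    rows[[p]] <- data.frame(
      animal = ped@id[cows[keep]], parity = p,
      herd = ped@herd[cows[keep]],
      fresh = as.Date(prof$fresh[keep, p], origin = "1970-01-01"),
      stringsAsFactors = FALSE)
  }
  recs <- do.call(rbind, rows)
  recs$hys <- hysClasses(recs$herd, recs$fresh)
  hysLevels <- sort(unique(recs$hys))
  hysEff <- withSeed(childSeed(seed, "hys"), {
    matrix(rnorm(length(hysLevels) * J, sd = rep(config@hysSd,
                                                 each = length(hysLevels))),
           length(hysLevels), J, dimnames = list(hysLevels, traits))
  })
  resid <- withSeed(childSeed(seed, "residual"), {
    matrix(rnorm(nrow(recs) * J), nrow(recs), J) %*% Es
  })
  vals <- config@parityEffects[recs$parity, , drop = FALSE] +
    hysEff[recs$hys, , drop = FALSE] +
    U[recs$animal, , drop = FALSE] + resid
  out <- data.frame(
    animal = rep(recs$animal, times = J),
    parity = rep(recs$parity, times = J),
    trait = rep(traits, each = nrow(recs)),
    value = as.vector(vals),
    hys = rep(recs$hys, times = J),
    fresh = rep(recs$fresh, times = J),
    stringsAsFactors = FALSE)
  attr(out, "hysEffects") <- hysEff
  attr(out, "residuals") <- resid
  out
}

# Calibrate the logistic slope linking the conception-status breeding
# value (percent scale) to the per-service conception probability so
# that the population SD of a cow's expected conception status matches
# the genetic SD of the trait. Quadrature over the BV distribution.
.csSlope <- function(p0, csSd) {
  if (csSd <= 0 || p0 <= 0 || p0 >= 1) return(0)
  z <- seq(-4, 4, length.out = 81)
  w <- exp(-z^2 / 2); w <- w / sum(w)
  expCs <- function(p) ifelse(p >= 1, 100,
                              ifelse(p <= 0, 0, -100 * p * log(p) / (1 - p)))
  sdAt <- function(s) {
    cs <- expCs(plogis(qlogis(p0) + s * csSd * z))
    m <- sum(w * cs)
    sqrt(sum(w * (cs - m)^2))
  }
  uniroot(function(s) sdAt(s) - csSd, c(1e-6, 2), extendInt = "upX",
          tol = 1e-8)$root
}

#' Simulate per-cow insemination sequences
#'
#' Bernoulli conception trials per service with probability
#' `logistic(logit(p0) + slope * BV_cs + herd effect)`; the slope is
#' calibrated so the population SD of the expected conception status
#' matches the genetic SD of the conception-status trait (the trait
#' model gives a variance on the percent scale, not a service-level
#' model, so this logistic process is a stand-in). A sequence stops at
#' conception, at `maxServices` (censored) or when the cow leaves the
#' herd mid-sequence (probability `serviceCullRate` per failed service).
#'
#' @inheritParams simulatePhenotypes
#' @return data.frame(animal, parity, service, date, outcome) with
#'   outcome in conceived/failed/censored; a censored cow-parity has no
#'   conceived row and its final row is marked censored.
#' @export
simulateInseminations <- function(ped, trueValues, config,
                                  seed = config@seed) {
  stopifnot(is(ped, "Pedigree"))
  traits <- colnames(config@G)
  csTrait <- if ("cs" %in% traits) "cs" else traits[length(traits)]
  uCs <- trueValues$breedingValues[, csTrait]
  prof <- .parityProfile(ped, config, seed)
  p0 <- config@baselineConception
  slope <- .csSlope(p0, sqrt(config@G[csTrait, csTrait]))
  herds <- sort(unique(ped@herd[prof$cows]))
  herdEff <- withSeed(childSeed(seed, "herd-fertility"),
                      setNames(rnorm(length(herds),
                                     sd = config@herdFertilitySd), herds))
  withSeed(childSeed(seed, "insem"), {
    out <- vector("list", length(prof$cows))
    for (ci in seq_along(prof$cows)) {
      i <- prof$cows[ci]
      pCow <- if (p0 <= 0 || p0 >= 1) p0 else
        plogis(qlogis(p0) + slope * uCs[ped@id[i]] +
               herdEff[[ped@herd[i]]])
      segs <- vector("list", prof$lastParity[ci])
      for (par in seq_len(prof$lastParity[ci])) {
        nServ <- 0L; outcome <- character(0)
        repeat {
          nServ <- nServ + 1L
          if (runif(1) < pCow) { outcome <- c(outcome, "conceived"); break }
          if (nServ >= config@maxServices) {
            outcome <- c(outcome, "censored"); break
          }
          if (runif(1) < config@serviceCullRate) {
            outcome <- c(outcome, "censored"); break
          }
          outcome <- c(outcome, "failed")
        }
        segs[[par]] <- data.frame(
          animal = ped@id[i], parity = par,
          service = seq_len(nServ),
          date = as.Date(prof$fresh[ci, par], origin = "1970-01-01") +
            60 + 21 * (seq_len(nServ) - 1L),
          outcome = outcome, stringsAsFactors = FALSE)
      }
      out[[ci]] <- do.call(rbind, segs)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Gene-drop SNP genotypes through a pedigree
#'
#' Founder alleles are drawn at frequencies uniform on `mafRange`; each
#' offspring receives one random allele per parent per SNP (unlinked
#' loci). Unknown parents transmit a fresh founder gamete. `nCausal`
#' SNPs receive bivariate effects for a protein-like and a
#' fertility-like trait, scaled so the expected causal genetic
#' covariance matches the corresponding 2 x 2 block of G.
#'
#' @inheritParams simulatePhenotypes
#' @return A [GenotypeMatrix-class]; when `nCausal > 0` the `causal`
#'   slot holds the causal SNP indices, their effect matrix, and the
#'   genomic values of every individual for the two causal traits.
#' @export
simulateGenotypes <- function(ped, config, seed = config@seed) {
  stopifnot(is(ped, "Pedigree"))
  m <- config@nSnps
  n <- length(ped@id)
  p <- .parentIdx(ped)
  withSeed(childSeed(seed, "genotypes"), {
    freq <- runif(m, config@mafRange[1L], config@mafRange[2L])
    H1 <- matrix(0L, n, m)
    H2 <- matrix(0L, n, m)
    gamete <- function(parent) {
      if (parent == 0L) return(as.integer(runif(m) < freq))
      pick <- runif(m) < 0.5
      ifelse(pick, H1[parent, ], H2[parent, ])
    }
    for (i in seq_len(n)) {
      H1[i, ] <- gamete(p$s[i])
      H2[i, ] <- gamete(p$d[i])
    }
    D <- H1 + H2
    storage.mode(D) <- "double"
    rownames(D) <- ped@id
    causal <- NULL
    if (config@nCausal > 0L) {
      traits <- colnames(config@G)
      ct <- intersect(c("protein", "cs"), traits)
      if (length(ct) < 2L) ct <- traits[seq_len(min(2L, length(traits)))]
      target <- config@G[ct, ct, drop = FALSE]
      idx <- sort(sample.int(m, config@nCausal))
      het <- sum(2 * freq[idx] * (1 - freq[idx]))
      beta <- matrix(rnorm(config@nCausal * length(ct)),
                     config@nCausal) %*% .matSqrt(target / het)
      colnames(beta) <- ct
      gv <- (D[, idx, drop = FALSE] -
             matrix(2 * freq[idx], n, length(idx), byrow = TRUE)) %*% beta
      causal <- list(snps = idx, effects = beta, geneticValues = gv)
    }
    if (config@genoMissingRate > 0) {
      missRate <- runif(m, 0, min(1, 2 * config@genoMissingRate))
      drop <- matrix(runif(n * m) < rep(missRate, each = n), n, m)
      D[drop] <- NA
    }
    chr <- rep(seq_len(29L), length.out = m)
    map <- data.frame(snp = sprintf("rs%05d", seq_len(m)), chr = chr,
                      pos = ave(seq_len(m), chr, FUN = seq_along) * 1000L,
                      stringsAsFactors = FALSE)
    genotypeMatrix(D, map = map, causal = causal)
  })
}
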