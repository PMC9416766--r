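# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately brute-force dense algebra, kept apart
# from the sparse implementation paths it checks.

# Dense GLS/BLUP: y = Xb + Zu + e with V = Z (A x G) Z' + R, solved by
# explicit matrix inversion. R is block-diagonal per animal-parity
# record with the observed submatrix of E.
denseBlupOracle <- function(ph, ped, cov, fixed = character(0)) {
  traits <- traitNames(cov)
  J <- length(traits)
  A <- tabularA(ped)
  G <- genCov(cov); E <- envCov(cov)
  GA <- kronecker(A, G)                       # animal-major x trait
  n <- nrow(ph)
  ids <- animalIds(ped)
  Z <- matrix(0, n, length(ids) * J)
  for (r in seq_len(n))
    Z[r, (match(ph$animal[r], ids) - 1L) * J +
         match(ph$trait[r], traits)] <- 1
  parity <- if ("parity" %in% colnames(ph)) ph$parity else rep(1L, n)
  key <- paste(ph$animal, parity)
  R <- matrix(0, n, n)
  for (k in unique(key)) {
    idx <- which(key == k)
    R[idx, idx] <- E[match(ph$trait[idx], traits),
                     match(ph$trait[idx], traits)]
  }
  X <- NULL
  if ("hys" %in% fixed)
    for (t in traits) for (h in sort(unique(ph$hys)))
      X <- cbind(X, as.numeric(ph$trait == t & ph$hys == h))
  if ("parity" %in% fixed)
    for (t in traits) for (p in setdiff(sort(unique(parity)), min(parity)))
      X <- cbind(X, as.numeric(ph$trait == t & parity == p))
  if (!is.null(X)) X <- X[, colSums(abs(X)) > 0, drop = FALSE]
  V <- Z %*% GA %*% t(Z) + R
  Vi <- solve(V)
  if (is.null(X)) {
    resid <- ph$value
    P <- Vi
  } else {
    bh <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% ph$value)
    resid <- ph$value - X %*% bh
    P <- Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi
  }
  u <- GA %*% t(Z) %*% Vi %*% resid
  pev <- GA - GA %*% t(Z) %*% P %*% Z %*% GA
  list(ebv = matrix(u, length(ids), J, byrow = TRUE,
                    dimnames = list(ids, traits)),
       pev = matrix(diag(pev), length(ids), J, byrow = TRUE,
                    dimnames = list(ids, traits)))
}

# Independent paternal-family pedigree: f families, each one sire,
# nd phenotyped dams and npd daughters per dam. Blocks are unrelated
# across families.
familyPedigree <- function(f, nd, npd) {
  ids <- character(0); sire <- character(0); dam <- character(0)
  sex <- character(0)
  for (k in seq_len(f)) {
    sid <- sprintf("S%03d", k)
    dids <- sprintf("D%03d_%02d", k, seq_len(nd))
    kids <- sprintf("C%03d_%02d_%d", k, rep(seq_len(nd), each = npd),
                    seq_len(npd))
    ids <- c(ids, sid, dids, kids)
    sire <- c(sire, NA, rep(NA, nd), rep(sid, nd * npd))
    dam <- c(dam, NA, rep(NA, nd), rep(dids, each = npd))
    sex <- c(sex, "M", rep("F", nd + nd * npd))
  }
  pedigree(id = ids, sire = sire, dam = dam, sex = sex)
}

# Random valid pedigree: founders then animals whose parents are drawn
# from earlier animals of the right sex (or unknown).
randomPedigree <- function(n, nFounders = max(4L, round(n / 5)),
                           pMissing = 0.1, seed = 1) {
  withr::with_seed(seed, {
    sex <- sample(c("M", "F"), n, replace = TRUE)
    sex[1:2] <- c("M", "F")
    id <- sprintf("R%04d", seq_len(n))
    sire <- rep(NA_character_, n)
    dam <- rep(NA_character_, n)
    for (i in seq.int(nFounders + 1L, n)) {
      males <- which(sex[seq_len(i - 1L)] == "M")
      females <- which(sex[seq_len(i - 1L)] == "F")
      if (length(males) && runif(1) > pMissing)
        sire[i] <- id[males[sample.int(length(males), 1L)]]
      if (length(females) && runif(1) > pMissing)
        dam[i] <- id[females[sample.int(length(females), 1L)]]
    }
    birth <- as.Date("2000-01-01") + seq_len(n) * 30
    pedigree(id = id, sire = sire, dam = dam, sex = sex, birth = birth,
             herd = sample(paste0("H", 1:3), n, replace = TRUE))
  })
}

# Random multi-trait evaluation instance on a random pedigree, with
# random trait missingness and herd-year-season classes.
randomBlupInstance <- function(seed, maxAnimals = 40L) {
  withr::with_seed(seed, {
    J <- sample(1:3, 1L)
    nA <- sample(10:maxAnimals, 1L)
    ped <- randomPedigree(nA, seed = seed + 1000L)
    L <- matrix(rnorm(J * J), J)
    G <- crossprod(L) + diag(J)
    L2 <- matrix(rnorm(J * J), J)
    E <- crossprod(L2) + diag(J)
    tr <- paste0("t", seq_len(J))
    dimnames(G) <- dimnames(E) <- list(tr, tr)
    cows <- animalIds(ped)[ped@sex == "F"]
    recs <- expand.grid(animal = cows, trait = tr,
                        stringsAsFactors = FALSE)
    recs <- recs[runif(nrow(recs)) > 0.25, ]
    recs$value <- rnorm(nrow(recs), 10, 3)
    recs$hys <- sample(paste0("h", 1:3), nrow(recs), replace = TRUE)
    ## hys must be shared across traits within a record
    recs$hys <- ave(recs$hys, recs$animal, FUN = function(z) z[1L])
    list(ped = ped, cov = traitCovariances(G, E), ph = recs)
  })
}
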