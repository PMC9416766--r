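#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("listOrNULL", c("list", "NULL"))

## ---------------------------------------------------------------------
## Pedigree
## ---------------------------------------------------------------------

#' Pedigree container
#'
#' Holds one row per animal with sire/dam links (NA for unknown parents),
#' sex, birth date and herd. Animals are stored in topological order so
#' that parents always precede their offspring; the constructor reorders
#' and the validity method rejects cyclic pedigrees, duplicated ids,
#' female sires and male dams.
#'
#' @slot id character animal identifiers, unique.
#' @slot sire,dam character parent identifiers or NA.
#' @slot sex character, "M" or "F".
#' @slot birth Date of birth (may be NA).
#' @slot herd character herd identifier (may be NA).
#' @seealso [pedigree()], [computeInbreeding()], [tabularA()], [aInverse()]
#' @export
setClass("Pedigree",
  representation(id = "character", sire = "character", dam = "character",
                 sex = "character", birth = "Date", herd = "character"))

setValidity("Pedigree", function(object) {
  msgs <- character(0)
  n <- length(object@id)
  if (anyDuplicated(object@id)) msgs <- c(msgs, "animal ids must be unique")
  for (sl in c("sire", "dam", "sex"))
    if (length(slot(object, sl)) != n)
      msgs <- c(msgs, paste0("slot '", sl, "' has wrong length"))
  if (length(msgs)) return(msgs)
  if (!all(object@sex %in% c("M", "F")))
    msgs <- c(msgs, "sex must be 'M' or 'F'")
  si <- match(object@sire, object@id)
  di <- match(object@dam, object@id)
  if (any(!is.na(object@sire) & is.na(si)))
    msgs <- c(msgs, "sire referenced but not present in pedigree")
  if (any(!is.na(object@dam) & is.na(di)))
    msgs <- c(msgs, "dam referenced but not present in pedigree")
  if (length(msgs)) return(msgs)
  own <- seq_len(n)
  if (any(si[!is.na(si)] >= own[!is.na(si)]) ||
      any(di[!is.na(di)] >= own[!is.na(di)]))
    msgs <- c(msgs, "pedigree is not in topological order (cycle?)")
  if (any(object@sex[si[!is.na(si)]] != "M"))
    msgs <- c(msgs, "all sires must be male")
  if (any(object@sex[di[!is.na(di)]] != "F"))
    msgs <- c(msgs, "all dams must be female")
  if (length(msgs)) msgs else TRUE
})

#' Construct a pedigree
#'
#' Builds a [Pedigree-class] from per-animal vectors, topologically
#' sorting so parents precede offspring. A cycle (an animal that is its
#' own ancestor) is an error.
#'
#' @param id Animal identifiers (coerced to character).
#' @param sire,dam Parent identifiers, NA for unknown.
#' @param sex "M"/"F" per animal.
#' @param birth Birth dates (Date or coercible); NA allowed.
#' @param herd Herd identifiers; NA allowed.
#' @return A [Pedigree-class] object.
#' @examples
#' ped <- pedigree(id = c("s", "d", "x"), sire = c(NA, NA, "s"),
#'                 dam = c(NA, NA, "d"), sex = c("M", "F", "F"))
#' computeInbreeding(ped)
#' @export
pedigree <- function(id, sire = NA, dam = NA, sex, birth = NULL, herd = NULL) {
  id <- as.character(id)
  n <- length(id)
  sire <- rep_len(as.character(sire), n)
  dam <- rep_len(as.character(dam), n)
  sex <- rep_len(as.character(sex), n)
  birth <- if (is.null(birth)) as.Date(rep(NA, n)) else
    rep_len(as.Date(birth), n)
  herd <- if (is.null(herd)) rep(NA_character_, n) else
    rep_len(as.character(herd), n)
  ord <- .topoOrder(id, sire, dam)
  new("Pedigree", id = id[ord], sire = sire[ord], dam = dam[ord],
      sex = sex[ord], birth = birth[ord], herd = herd[ord])
}

# Kahn-style topological sort over parent links; signals cycles.
.topoOrder <- function(id, sire, dam) {
  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != n) stop("pedigree contains a cycle")
  out
}

#' @describeIn Pedigree-class number of animals
#' @param x,object A Pedigree.
#' @export
setMethod("length", "Pedigree", function(x) length(x@id))

#' @describeIn Pedigree-class animal identifiers
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))

#' @rdname Pedigree-class
#' @export
setMethod("animalIds", "Pedigree", function(x) x@id)

#' @rdname Pedigree-class
#' @param row.names,optional,... passed on conventionally, unused.
#' @export
setMethod("as.data.frame", "Pedigree",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(id = x@id, sire = x@sire, dam = x@dam, sex = x@sex,
               birth = x@birth, herd = x@herd, stringsAsFactors = FALSE)
  })

setMethod("show", "Pedigree", function(object) {
  n <- length(object@id)
  founders <- sum(is.na(object@sire) & is.na(object@dam))
  cat("Pedigree with", n, "animals (", founders, "founders,",
      sum(object@sex == "F"), "female )\n")
  if (!all(is.na(object@birth)))
    cat("  birth years:", format(min(object@birth, na.rm = TRUE), "%Y"), "-",
        format(max(object@birth, na.rm = TRUE), "%Y"), "\n")
})

## ---------------------------------------------------------------------
## TraitCovariances
## ---------------------------------------------------------------------

#' Paired genetic and environmental covariance matrices
#'
#' The central parameter container: a genetic covariance matrix G and an
#' environmental covariance matrix E over the same ordered trait set.
#' The phenotypic covariance is P = G + E. Optional standard errors of
#' the elements (from average-information REML) may be attached.
#'
#' @slot G,E Symmetric trait covariance matrices with identical dimnames.
#' @slot se Optional list with elements `G` and `E` of elementwise SEs.
#' @seealso [traitCovariances()], [heritability()], [geneticCorrelation()]
#' @export
setClass("TraitCovariances",
  representation(G = "matrix", E = "matrix", se = "listOrNULL"))

setValidity("TraitCovariances", function(object) {
  msgs <- character(0)
  if (!identical(dim(object@G), dim(object@E)))
    msgs <- c(msgs, "G and E must have identical dimensions")
  if (is.null(dimnames(object@G)) ||
      !identical(dimnames(object@G), dimnames(object@E)))
    msgs <- c(msgs, "G and E must carry identical trait dimnames")
  if (!isSymmetric(unname(object@G), tol = 1e-6) ||
      !isSymmetric(unname(object@E), tol = 1e-6))
    msgs <- c(msgs, "G and E must be symmetric")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TraitCovariances object
#'
#' @param G,E Symmetric covariance matrices with matching trait labels
#'   (dimnames); unlabeled matrices get labels `t1`, `t2`, ...
#' @param se Optional list(G =, E =) of elementwise standard errors.
#' @return A [TraitCovariances-class] object.
#' @export
traitCovariances <- function(G, E, se = NULL) {
  G <- as.matrix(G); E <- as.matrix(E)
  if (is.null(dimnames(G))) {
    lab <- paste0("t", seq_len(nrow(G)))
    dimnames(G) <- list(lab, lab)
  }
  if (is.null(dimnames(E))) dimnames(E) <- dimnames(G)
  new("TraitCovariances", G = symmetrize(G), E = symmetrize(E), se = se)
}

#' @describeIn TraitCovariances-class genetic covariance matrix
#' @param x,object A TraitCovariances object.
#' @export
setGeneric("genCov", function(x) standardGeneric("genCov"))
#' @rdname TraitCovariances-class
#' @export
setMethod("genCov", "TraitCovariances", function(x) x@G)

#' @describeIn TraitCovariances-class environmental covariance matrix
#' @export
setGeneric("envCov", function(x) standardGeneric("envCov"))
#' @rdname TraitCovariances-class
#' @export
setMethod("envCov", "TraitCovariances", function(x) x@E)

#' @describeIn TraitCovariances-class phenotypic covariance G + E
#' @export
setGeneric("phenCov", function(x) standardGeneric("phenCov"))
#' @rdname TraitCovariances-class
#' @export
setMethod("phenCov", "TraitCovariances", function(x) x@G + x@E)

#' @describeIn TraitCovariances-class trait labels
#' @export
setGeneric("traitNames", function(x) standardGeneric("traitNames"))
#' @rdname TraitCovariances-class
#' @export
setMethod("traitNames", "TraitCovariances", function(x) colnames(x@G))

#' @rdname TraitCovariances-class
#' @param i,j,...,drop subsetting by trait label or index.
#' @export
setMethod("[", "TraitCovariances", function(x, i, j, ..., drop = FALSE) {
  traitCovariances(x@G[i, i, drop = FALSE], x@E[i, i, drop = FALSE])
})

setMethod("show", "TraitCovariances", function(object) {
  tr <- traitNames(object)
  cat("TraitCovariances over", length(tr), "traits:",
      paste(tr, collapse = ", "), "\n")
  h2 <- round(diag(object@G) / diag(phenCov(object)), 3)
  cat("  heritabilities:", paste(h2, collapse = " "), "\n")
  if (!is.null(object@se)) cat("  elementwise SEs attached\n")
})

## ---------------------------------------------------------------------
## IndexSpec
## ---------------------------------------------------------------------

#' Selection-index specification
#'
#' Named economic weights b (index coefficients per trait unit) together
#' with the favorable direction of each trait (+1, or -1 for traits where
#' lower values are economically favorable, e.g. somatic cell score).
#'
#' @slot coefficients Named numeric vector of index weights.
#' @slot favorable Named numeric vector of +1/-1, same names.
#' @seealso [indexSpec()], [indexFractions()], [expectedGains()]
#' @export
setClass("IndexSpec",
  representation(coefficients = "numeric", favorable = "numeric"))

setValidity("IndexSpec", function(object) {
  msgs <- character(0)
  if (is.null(names(object@coefficients)))
    msgs <- c(msgs, "coefficients must be named by trait")
  if (!identical(names(object@coefficients), names(object@favorable)))
    msgs <- c(msgs, "favorable signs must match coefficient names")
  if (!all(object@favorable %in% c(-1, 1)))
    msgs <- c(msgs, "favorable must be +1 or -1")
  if (all(object@coefficients == 0))
    msgs <- c(msgs, "at least one coefficient must be nonzero")
  if (length(msgs)) msgs else TRUE
})

#' Construct a selection-index specification
#'
#' @param coefficients Named numeric vector of index weights (economic
#'   units per trait unit).
#' @param negative Character vector of trait names whose favorable
#'   direction is negative.
#' @return An [IndexSpec-class].
#' @export
indexSpec <- function(coefficients, negative = character(0)) {
  fav <- setNames(rep(1, length(coefficients)), names(coefficients))
  fav[names(fav) %in% negative] <- -1
  new("IndexSpec", coefficients = coefficients, favorable = fav)
}

#' @describeIn IndexSpec-class the coefficient vector b
#' @param x,object An IndexSpec.
#' @export
setGeneric("indexCoefficients", function(x) standardGeneric("indexCoefficients"))
#' @rdname IndexSpec-class
#' @export
setMethod("indexCoefficients", "IndexSpec", function(x) x@coefficients)

#' @describeIn IndexSpec-class favorable direction (+1/-1) per trait
#' @export
setGeneric("favorableSign", function(x) standardGeneric("favorableSign"))
#' @rdname IndexSpec-class
#' @export
setMethod("favorableSign", "IndexSpec", function(x) x@favorable)

setMethod("show", "IndexSpec", function(object) {
  cat("IndexSpec with", sum(object@coefficients != 0), "weighted traits\n")
  print(object@coefficients)
})

## ---------------------------------------------------------------------
## RemlFit
## ---------------------------------------------------------------------

#' REML variance-component fit
#'
#' Result of [remlFit()]: estimated covariance matrices, the restricted
#' log-likelihood trace across iterations, convergence status and the
#' method that produced the final iterate.
#'
#' @slot covariances Estimated [TraitCovariances-class] (SEs attached when
#'   the average-information step ran).
#' @slot logLik Numeric vector, restricted log-likelihood per iteration.
#' @slot converged Logical.
#' @slot iterations Integer iteration count.
#' @slot method Character: "em", "ai" or "em-then-ai".
#' @export
setClass("RemlFit",
  representation(covariances = "TraitCovariances", logLik = "numeric",
                 converged = "logical", iterations = "integer",
                 method = "character"))

#' @describeIn RemlFit-class the estimated covariances
#' @param x,object A RemlFit.
#' @export
setGeneric("covariances", function(x) standardGeneric("covariances"))
#' @rdname RemlFit-class
#' @export
setMethod("covariances", "RemlFit", function(x) x@covariances)

#' @rdname RemlFit-class
#' @param ... unused.
#' @export
setMethod("logLik", "RemlFit", function(object, ...) {
  ll <- object@logLik[length(object@logLik)]
  structure(ll, class = "logLik")
})

setMethod("show", "RemlFit", function(object) {
  cat("RemlFit (", object@method, "), ", object@iterations, " iterations, ",
      if (object@converged) "converged" else "NOT converged", "\n", sep = "")
  cat("  restricted logLik:", format(object@logLik[length(object@logLik)]), "\n")
  show(object@covariances)
})

## ---------------------------------------------------------------------
## EvaluationResult
## ---------------------------------------------------------------------

#' Genetic evaluation result
#'
#' EBVs (animal x trait), fixed-effect solutions, optional reliabilities
#' and the genetic-base cohort to which EBVs were rebased (the cohort's
#' mean EBV is zero for every trait).
#'
#' @slot ebv Numeric matrix, animals x traits.
#' @slot reliability Matrix of r-squared in [0, 1), or NULL.
#' @slot fixedSolutions Named numeric vector of fixed-effect estimates.
#' @slot baseCohort Character ids of the base cohort (may be empty when
#'   no rebasing was applied).
#' @export
setClass("EvaluationResult",
  representation(ebv = "matrix", reliability = "matrixOrNULL",
                 fixedSolutions = "numeric", baseCohort = "character"))

#' @describeIn EvaluationResult-class EBV matrix (animals x traits)
#' @param x,object An EvaluationResult.
#' @export
setGeneric("ebv", function(x) standardGeneric("ebv"))
#' @rdname EvaluationResult-class
#' @export
setMethod("ebv", "EvaluationResult", function(x) x@ebv)

#' @describeIn EvaluationResult-class reliability matrix or NULL
#' @export
setGeneric("reliabilities", function(x) standardGeneric("reliabilities"))
#' @rdname EvaluationResult-class
#' @export
setMethod("reliabilities", "EvaluationResult", function(x) x@reliability)

#' @describeIn EvaluationResult-class fixed-effect solutions
#' @export
setGeneric("fixedSolutions", function(x) standardGeneric("fixedSolutions"))
#' @rdname EvaluationResult-class
#' @export
setMethod("fixedSolutions", "EvaluationResult", function(x) x@fixedSolutions)

setMethod("show", "EvaluationResult", function(object) {
  cat("EvaluationResult:", nrow(object@ebv), "animals x",
      ncol(object@ebv), "traits\n")
  if (length(object@baseCohort))
    cat("  rebased to a cohort of", length(object@baseCohort), "animals\n")
  if (!is.null(object@reliability))
    cat("  mean reliability:",
        round(mean(object@reliability, na.rm = TRUE), 3), "\n")
})

## ---------------------------------------------------------------------
## GenotypeMatrix
## ---------------------------------------------------------------------

#' SNP genotype container
#'
#' Dosage matrix (individuals x SNPs, values 0/1/2 or NA for missing)
#' plus a marker map with chromosome and position.
#'
#' @slot dosage Numeric matrix, individuals in rows.
#' @slot map data.frame with columns snp, chr, pos (one row per SNP).
#' @slot causal Optional list describing simulated causal architecture
#'   (snp indices, effect matrix, genetic values); NULL for real data.
#' @seealso [genotypeMatrix()], [qcFilter()], [ibsKinship()], [gwasScan()]
#' @export
setClass("GenotypeMatrix",
  representation(dosage = "matrix", map = "data.frame", causal = "listOrNULL"))

setValidity("GenotypeMatrix", function(object) {
  msgs <- character(0)
  if (ncol(object@dosage) != nrow(object@map))
    msgs <- c(msgs, "map must have one row per dosage column")
  if (!all(c("snp", "chr", "pos") %in% colnames(object@map)))
    msgs <- c(msgs, "map needs columns snp, chr, pos")
  d <- object@dosage
  if (!all(d %in% c(0, 1, 2) | is.na(d)))
    msgs <- c(msgs, "dosages must be 0, 1, 2 or NA")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosage Individuals x SNPs matrix of allele dosages (0/1/2, NA
#'   for missing). Row names are individual ids.
#' @param map Optional data.frame(snp, chr, pos); defaults to one
#'   chromosome with unit spacing.
#' @param causal Optional simulated-truth list (see
#'   [simulateGenotypes()]).
#' @return A [GenotypeMatrix-class].
#' @export
genotypeMatrix <- function(dosage, map = NULL, causal = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(map))
    map <- data.frame(snp = colnames(dosage) %||% paste0("snp", seq_len(ncol(dosage))),
                      chr = 1L, pos = seq_len(ncol(dosage)),
                      stringsAsFactors = FALSE)
  colnames(dosage) <- map$snp
  new("GenotypeMatrix", dosage = dosage, map = map, causal = causal)
}

#' @describeIn GenotypeMatrix-class dosage matrix
#' @param x,object A GenotypeMatrix.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname GenotypeMatrix-class
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosage)

#' @describeIn GenotypeMatrix-class marker map
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))
#' @rdname GenotypeMatrix-class
#' @export
setMethod("snpMap", "GenotypeMatrix", function(x) x@map)

#' @describeIn GenotypeMatrix-class number of SNPs
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))
#' @rdname GenotypeMatrix-class
#' @export
setMethod("nSnps", "GenotypeMatrix", function(x) ncol(x@dosage))

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@dosage), "individuals x",
      ncol(object@dosage), "SNPs\n")
  miss <- mean(is.na(object@dosage))
  if (miss > 0) cat("  missing rate:", signif(miss, 3), "\n")
  if (!is.null(object@causal))
    cat("  simulated causal SNPs:", length(object@causal$snps), "\n")
})

## ---------------------------------------------------------------------
## GwasResult
## ---------------------------------------------------------------------

#' Mixed-model association scan result
#'
#' Per-SNP allele substitution effects, standard errors, p-values, minor
#' allele frequencies and call rates from [gwasScan()], with the null
#' model's variance components attached.
#'
#' @slot table data.frame(snp, chr, pos, effect, se, p, maf, callRate).
#' @slot n Integer, individuals analyzed.
#' @slot h2 Pseudo-heritability from the null model.
#' @slot trait Character label of the response.
#' @export
setClass("GwasResult",
  representation(table = "data.frame", n = "integer", h2 = "numeric",
                 trait = "character"))

#' @describeIn GwasResult-class per-SNP results table
#' @param x,object A GwasResult.
#' @export
setGeneric("gwasTable", function(x) standardGeneric("gwasTable"))
#' @rdname GwasResult-class
#' @export
setMethod("gwasTable", "GwasResult", function(x) x@table)

setMethod("show", "GwasResult", function(object) {
  cat("GwasResult for '", object@trait, "': ", nrow(object@table),
      " SNPs, n = ", object@n, "\n", sep = "")
  cat("  pseudo-heritability:", round(object@h2, 3), "\n")
  cat("  min p:", format(min(object@table$p), digits = 3), "\n")
})
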