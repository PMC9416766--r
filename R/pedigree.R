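## Pedigree algebra: inbreeding, numerator relationship matrix A, sparse
## A-inverse by Henderson's rules, unknown-parent group assignment.

# Parent index vectors (0L = unknown) for a Pedigree in topological order.
.parentIdx <- function(ped) {
  si <- match(ped@sire, ped@id); si[is.na(si)] <- 0L
  di <- match(ped@dam, ped@id); di[is.na(di)] <- 0L
  list(s = as.integer(si), d = as.integer(di))
}

#' Inbreeding coefficients
#'
#' Computes the inbreeding coefficient F of every animal by the
#' Meuwissen--Luo algorithm: F_i is the kinship of the parents, obtained
#' from the gene-contribution decomposition A = L D L' without forming A.
#' Animals with an unknown parent get F = 0 (phantom founders are
#' non-inbred).
#'
#' @param ped A [Pedigree-class].
#' @return Named numeric vector of F, in pedigree order.
#' @references Meuwissen & Luo (1992) Genet Sel Evol 24:305.
#' @export
computeInbreeding <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  p <- .parentIdx(ped)
  s <- p$s; d <- p$d
  n <- length(s)
  F <- numeric(n)
  Dv <- numeric(n)  # Mendelian variances of processed animals
  for (i in seq_len(n)) {
    if (s[i] == 0L || d[i] == 0L) {
      F[i] <- 0
    } else if (i > 1L && s[i] == s[i - 1L] && d[i] == d[i - 1L]) {
      F[i] <- F[i - 1L]  # full sibs share F
    } else {
      ## back-propagate gene contributions of a pseudo-animal with
      ## parents (s_i, d_i): F_i = d_pseudo + sum_j L_j^2 D_j - 1
      v <- numeric(i)
      v[s[i]] <- v[s[i]] + 0.5
      v[d[i]] <- v[d[i]] + 0.5
      acc <- 0.5 - 0.25 * (F[s[i]] + F[d[i]])  # d of the pseudo-animal
      for (j in rev(seq_len(max(s[i], d[i])))) {
        if (v[j] == 0) next
        if (s[j] > 0L) v[s[j]] <- v[s[j]] + 0.5 * v[j]
        if (d[j] > 0L) v[d[j]] <- v[d[j]] + 0.5 * v[j]
        acc <- acc + v[j]^2 * Dv[j]
      }
      F[i] <- acc - 1
    }
    Dv[i] <- 1 -
      (if (s[i] > 0L) 0.25 * (1 + F[s[i]]) else 0) -
      (if (d[i] > 0L) 0.25 * (1 + F[d[i]]) else 0)
  }
  setNames(F, ped@id)
}

#' Dense tabular relationship matrix
#'
#' Builds the numerator relationship matrix A by the tabular method:
#' a_ii = 1 + F_i and a_ij = (a_i,sire(j) + a_i,dam(j)) / 2. Intended as
#' an exact oracle at desk scale; requests beyond `maxAnimals` are
#' refused so the sparse inverse path must be used instead.
#'
#' @param ped A [Pedigree-class].
#' @param maxAnimals Dense-size guard (default 2000).
#' @return Dense symmetric matrix with animal ids as dimnames.
#' @export
tabularA <- function(ped, maxAnimals = 2000L) {
  stopifnot(is(ped, "Pedigree"))
  n <- length(ped@id)
  if (n > maxAnimals)
    stop("pedigree has ", n, " animals; dense tabular A is limited to ",
         maxAnimals, " (raise maxAnimals or use aInverse)")
  p <- .parentIdx(ped)
  s <- p$s; d <- p$d
  A <- matrix(0, n, n, dimnames = list(ped@id, ped@id))
  for (i in seq_len(n)) {
    asd <- if (s[i] > 0L && d[i] > 0L) A[s[i], d[i]] else 0
    A[i, i] <- 1 + 0.5 * asd
    if (i > 1L) {
      js <- seq_len(i - 1L)
      row <- 0.5 * ((if (s[i] > 0L) A[js, s[i]] else 0) +
                    (if (d[i] > 0L) A[js, d[i]] else 0))
      A[i, js] <- row
      A[js, i] <- row
    }
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds A-inverse directly by Henderson's rules with inbreeding: each
#' animal contributes alpha_i = 1/d_i to at most a 3 x 3 block over
#' (animal, sire, dam), where d_i = 1/2 - (F_s + F_d)/4 is the
#' Mendelian-sampling variance (adjusted when a parent is unknown).
#'
#' When `groups` is supplied (see [assignGroups()]), unknown parent slots
#' point at phantom-parent group columns in the Westell/Quaas--Pollak
#' construction: the returned matrix has one extra row/column per group,
#' and group "parents" are treated as non-inbred.
#'
#' @param ped A [Pedigree-class].
#' @param inbreeding Optional precomputed F vector (pedigree order);
#'   computed via [computeInbreeding()] when NULL. Pass `rep(0, n)` for an
#'   inbreeding-ignorant inverse.
#' @param groups Optional group map from [assignGroups()].
#' @return A symmetric sparse [Matrix::dsCMatrix-class] with animal ids
#'   (then group labels) as dimnames.
#' @export
aInverse <- function(ped, inbreeding = NULL, groups = NULL) {
  stopifnot(is(ped, "Pedigree"))
  p <- .parentIdx(ped)
  s <- p$s; d <- p$d
  n <- length(s)
  F <- if (is.null(inbreeding)) computeInbreeding(ped) else
    rep_len(as.numeric(inbreeding), n)
  labels <- ped@id
  if (!is.null(groups)) {
    glab <- sort(unique(groups$group))
    labels <- c(ped@id, glab)
    gs <- groups[groups$slot == "sire", ]
    gd <- groups[groups$slot == "dam", ]
    s[match(gs$animal, ped@id)] <- n + match(gs$group, glab)
    d[match(gd$animal, ped@id)] <- n + match(gd$group, glab)
  }
  Fx <- c(F, rep(0, length(labels) - n))  # groups are non-inbred means
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  addTriplet <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (i in seq_len(n)) {
    pa <- c(s[i], d[i])
    pa <- pa[pa > 0L]
    di <- 1 - sum(0.25 * (1 + Fx[pa]))
    if (length(pa) == 0L) di <- 1
    if (di <= 0) stop("non-positive Mendelian variance for animal ", ped@id[i])
    al <- 1 / di
    addTriplet(i, i, al)
    for (q in pa) {
      addTriplet(i, q, -0.5 * al)
      addTriplet(q, i, -0.5 * al)
      addTriplet(q, q, 0.25 * al)
    }
    if (length(pa) == 2L) {
      addTriplet(pa[1L], pa[2L], 0.25 * al)
      addTriplet(pa[2L], pa[1L], 0.25 * al)
    }
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(labels), length(labels)),
                            dimnames = list(labels, labels))
  methods::as(Matrix::forceSymmetric(m), "symmetricMatrix")
}

#' Assign unknown-parent genetic groups
#'
#' Maps every unknown parent slot to exactly one genetic group. Groups
#' enter the evaluation as phantom-parent columns (see [aInverse()]),
#' absorbing the mean merit of animals with unknown ancestry.
#'
#' Rules: `"by_sex"` groups by the sex of the animal with the unknown
#' parent (the two-group national convention for variance-component data
#' sets); `"by_sex_and_birth_year"` crosses sex with birth year;
#' `"custom"` applies `fun(animal_row, slot)` returning a label.
#'
#' @param ped A [Pedigree-class].
#' @param rule One of "by_sex", "by_sex_and_birth_year", "custom".
#' @param fun Labeling function for rule = "custom".
#' @return data.frame(animal, slot, group); zero rows when no parent is
#'   unknown.
#' @export
assignGroups <- function(ped, rule = c("by_sex", "by_sex_and_birth_year",
                                       "custom"), fun = NULL) {
  rule <- match.arg(rule)
  df <- as.data.frame(ped)
  rows <- list()
  for (slot in c("sire", "dam")) {
    unk <- which(is.na(df[[slot]]))
    ## founders (both parents unknown, first generation) are their own base
    ## population only when they in turn have offspring links; every
    ## unknown slot still needs a group so the genetic-effect design is
    ## complete.
    if (!length(unk)) next
    lab <- switch(rule,
      by_sex = paste0("g_", df$sex[unk]),
      by_sex_and_birth_year = {
        if (all(is.na(df$birth[unk])))
          stop("rule 'by_sex_and_birth_year' needs birth dates")
        paste0("g_", df$sex[unk], "_", format(df$birth[unk], "%Y"))
      },
      custom = {
        if (is.null(fun)) stop("rule 'custom' needs a labeling function")
        vapply(unk, function(i) as.character(fun(df[i, ], slot)), "")
      })
    rows[[slot]] <- data.frame(animal = df$id[unk], slot = slot,
                               group = lab, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(animal = character(0), slot = character(0),
                      group = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write the pedigree CSV interchange format
#'
#' Columns: id, sire, dam, sex, birth_date, herd; empty parent fields are
#' unknown parents.
#'
#' @param file Path to a CSV file.
#' @return [readPedigreeCsv()] returns a [Pedigree-class].
#' @export
readPedigreeCsv <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE,
                 colClasses = c(id = "character", sire = "character",
                                dam = "character"))
  df$sire[!nzchar(df$sire %||% "")] <- NA_character_
  df$dam[!nzchar(df$dam %||% "")] <- NA_character_
  pedigree(id = df$id, sire = df$sire, dam = df$dam, sex = df$sex,
           birth = as.Date(df$birth_date), herd = df$herd)
}

#' @rdname readPedigreeCsv
#' @param ped A [Pedigree-class] to write.
#' @export
writePedigreeCsv <- function(ped, file) {
  df <- as.data.frame(ped)
  names(df)[names(df) == "birth"] <- "birth_date"
  df$sire[is.na(df$sire)] <- ""
  df$dam[is.na(df$dam)] <- ""
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a sparse symmetric matrix as coordinate text
#'
#' Row, column, value triplets (1-based, upper triangle) with a header
#' line; the companion reader restores the symmetric matrix.
#'
#' @param m A (sparse) symmetric matrix.
#' @param file Output path.
#' @export
writeSparseTriplets <- function(m, file) {
  tm <- methods::as(methods::as(m, "generalMatrix"), "TsparseMatrix")
  keep <- tm@i <= tm@j
  df <- data.frame(row = tm@i[keep] + 1L, col = tm@j[keep] + 1L,
                   value = tm@x[keep])
  df <- df[order(df$row, df$col), ]
  write.table(df, file, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(file)
}

#' @rdname writeSparseTriplets
#' @param n Matrix dimension (inferred from the triplets when NULL).
#' @export
readSparseTriplets <- function(file, n = NULL) {
  df <- read.table(file, header = TRUE)
  n <- n %||% max(df$row, df$col)
  m <- Matrix::sparseMatrix(i = df$row, j = df$col, x = df$value,
                            dims = c(n, n), symmetric = TRUE)
  m
}
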