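#' Canonical trait ordering of the Israeli breeding index
#'
#' The nine traits of the Israeli Holstein selection index PD19, in the
#' order used by every bundled parameter set: milk, fat and protein yield
#' (kg), somatic cell score (SCS), conception status (CS, percent),
#' herd-life (days), persistency (percent), dystocia and stillbirth rate
#' (percent).
#'
#' @return Character vector of length nine.
#' @export
indexTraits <- function() {
  c("milk", "fat", "protein", "scs", "cs",
    "herdlife", "persistency", "dystocia", "stillbirth")
}

#' Historical coefficients of the Israeli breeding index
#'
#' Index coefficients (economic weights per trait unit) of the Israeli
#' national breeding index at each revision since 1985. Traits absent
#' from an early index carry a zero weight. SCS, dystocia and stillbirth
#' are economically favorable in the negative direction.
#'
#' @param year Revision year as character or number; defaults to the 2019
#'   index (PD19).
#' @return An [IndexSpec-class] holding the coefficients for that revision.
#' @examples
#' indexCoefficients(pd19IndexWeights())
#' @export
pd19IndexWeights <- function(year = "2019") {
  year <- as.character(year)
  tab <- .indexHistory()
  if (!year %in% colnames(tab))
    stop("no index revision for year ", year,
         "; available: ", paste(colnames(tab), collapse = ", "))
  indexSpec(tab[, year],
            negative = c("scs", "dystocia", "stillbirth"))
}

.indexHistory <- function() {
  yrs <- c("1985", "1990", "1991", "1996", "2000", "2001",
           "2004", "2007", "2011", "2016", "2019")
  m <- matrix(0, nrow = 9L, ncol = length(yrs),
              dimnames = list(indexTraits(), yrs))
  m["milk", ]    <- c(0.51, 0, -0.274, -0.274, -0.274, -0.22, 0, 0, 0, 0, 0)
  m["fat", ]     <- c(14, 0, 6.41, 6.41, 6.41, 8.5, 6.3, 6.3, 7.9, 8.48, 9.94)
  m["protein", ] <- c(0, 1.0, 34.85, 34.85, 34.85, 31.0, 25.4, 25.4,
                      23.7, 21.2, 19.88)
  m["scs", c("1996", "2000", "2001", "2004", "2007", "2011", "2016",
             "2019")] <- -300
  m["cs", c("2000", "2001", "2004", "2007", "2011", "2016", "2019")] <- 26
  m["herdlife", c("2004", "2007", "2011", "2016", "2019")] <- 0.6
  m["persistency", c("2007", "2011", "2016", "2019")] <- 10
  m["dystocia", c("2007", "2011", "2016", "2019")] <- -3
  m["stillbirth", c("2007", "2011", "2016", "2019")] <- -6
  m
}

#' First-parity variance components of the Israeli Holstein population
#'
#' Genetic and environmental covariance matrices among the nine index
#' traits, estimated by multi-trait REML from first-parity records of
#' Israeli Holstein cows born 2008--2016. These published national
#' estimates are the default parameterization of the synthetic-data
#' generator and the input to the selection-index computations.
#'
#' @return A [TraitCovariances-class] object with 9 x 9 genetic and
#'   environmental matrices in trait units squared.
#' @examples
#' vc <- ilTraitCovariances()
#' heritability(vc, "protein")
#' geneticCorrelation(vc, "protein", "cs")
#' @export
ilTraitCovariances <- function() {
  tr <- indexTraits()
  G <- matrix(c(
    1104690.4, 18187.0, 24365.4,  109.7, -2604.3, 20562.9, 1428.5, -397.7,  13.7,
      18187.0,  1491.4,   641.0,    1.7,   -78.9,   789.7,   17.7,   -0.2,   4.3,
      24365.4,   641.0,   752.4,    3.0,   -82.3,   385.9,   18.8,   -8.8,   3.9,
        109.7,     1.7,     3.0,    0.3,    -1.1,   -29.5,   -0.2,    0.1,   0.1,
      -2604.3,   -78.9,   -82.3,   -1.1,    62.1,   917.6,    2.4,  -10.3,  -4.7,
      20562.9,   789.7,   385.9,  -29.5,   917.6, 48508.9,  521.4, -215.0, -122.3,
       1428.5,    17.7,    18.8,   -0.2,     2.4,   521.4,   34.7,   -0.1,  -0.3,
       -397.7,    -0.2,    -8.8,    0.1,   -10.3,  -215.0,   -0.1,   27.0,  11.2,
         13.7,     4.3,     3.9,    0.1,    -4.7,  -122.3,   -0.3,   11.2,   8.8),
    9, 9, byrow = TRUE, dimnames = list(tr, tr))
  E <- matrix(c(
    1072573.5, 28444.7, 29929.6,  -67.7,  2086.5, 89681.7, -481.4, -767.6, -885.6,
      28444.7,  1488.6,   872.9,   -2.2,     2.8,  2376.4,  -10.0,  -26.5,  -26.7,
      29929.6,   872.9,   911.2,   -1.3,    43.1,  2455.3,  -14.3,  -22.8,  -26.5,
        -67.7,    -2.2,    -1.3,    0.9,     1.1,   -13.4,   -0.4,   -0.3,   -0.2,
       2086.5,     2.8,    43.1,    1.1,  1101.3,  2098.0,  -10.3,  -24.7,  -11.8,
      89681.7,  2376.4,  2455.3,  -13.4,  2098.0, 332822.6,  158.0,  704.8,   29.6,
       -481.4,   -10.0,   -14.3,   -0.4,   -10.3,   158.0,  123.2,    4.3,    3.2,
       -767.6,   -26.5,   -22.8,   -0.3,   -24.7,   704.8,    4.3,  669.1,  149.5,
       -885.6,   -26.7,   -26.5,   -0.2,   -11.8,    29.6,    3.2,  149.5,  423.0),
    9, 9, byrow = TRUE, dimnames = list(tr, tr))
  traitCovariances(G, E)
}

#' Published national gain summary for the PD19 index
#'
#' The published summary of the Israeli national evaluation for cows born
#' 2008--2016: per-trait genetic standard deviation, fraction of the
#' index, expected 10-year genetic gain under index selection, realized
#' genetic trend (with standard error) from the regression of cow EBV on
#' birth date, and the standardized realized-minus-expected discrepancy
#' (sign-reversed for the negative-favorable traits). The total economic
#' gain of the index is attached as the `"teg"` attribute (expected,
#' realized, realized SE).
#'
#' These printed values serve as inputs for trend comparisons and as
#' cross-checks for the index engine; realized trends are observable only
#' from the national data, not from first principles.
#'
#' @return A data.frame with one row per trait.
#' @export
ilGainSummary <- function() {
  out <- data.frame(
    trait = indexTraits(),
    geneticSd  = c(1051, 38.6, 27.4, 0.55, 7.9, 220, 5.9, 5.2, 3),
    fraction   = c(0, 0.252, 0.358, 0.108, 0.135, 0.087, 0.039, 0.01, 0.012),
    expected   = c(1073.4, 46.5, 33.9, -0.12, 0.3, 152.1, 2.4, -1.39, -0.34),
    realized   = c(699.4, 40.0, 32.5, -0.194, 1.91, 209.1, 1.00, -0.800, 0.233),
    realizedSe = c(3.5, 0.1, 0.1, 0.002, 0.02, 0.6, 0.02, 0.014, 0.009),
    discrepancy = c(-0.36, -0.17, -0.05, 0.13, 0.2, 0.26, -0.24, -0.11, -0.19),
    stringsAsFactors = FALSE)
  attr(out, "teg") <- c(expected = 1300.5, realized = 1300.7, realizedSe = 3.34)
  out
}
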