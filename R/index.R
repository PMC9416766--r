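## Selection-index engine: index fractions, expected genetic gains under
## index selection, total economic gain, selection-intensity calibration
## and the standardized realized-vs-expected discrepancy table.

#' Genetic standard deviations
#'
#' g_j = sqrt of the genetic variance of each trait.
#'
#' @param cov A [TraitCovariances-class].
#' @return Named numeric vector in trait units.
#' @export
geneticSd <- function(cov) {
  g <- diag(genCov(cov))
  if (any(g < 0)) stop("negative genetic variance on the diagonal")
  sqrt(g)
}

#' Fraction of the index attributable to each trait
#'
#' c_j = |b_j g_j| / sum_j |b_j g_j|: the share of the selection index
#' carried by trait j, where b_j is the economic weight and g_j the
#' genetic SD. The fractions sum to one and are invariant to rescaling
#' all weights by a positive constant.
#'
#' @param spec An [IndexSpec-class].
#' @param g Named genetic SDs (as from [geneticSd()]); matched to the
#'   coefficient names.
#' @return Named fractions summing to 1.
#' @examples
#' indexFractions(pd19IndexWeights(), geneticSd(ilTraitCovariances()))
#' @export
indexFractions <- function(spec, g) {
  b <- indexCoefficients(spec)
  stopifnot(length(b) == length(g))
  if (!is.null(names(g))) g <- g[names(b)]
  w <- abs(b * g)
  if (sum(w) == 0) stop("all index contributions are zero")
  w / sum(w)
}

#' Expected genetic gains under index selection
#'
#' The vector of expected genetic changes per trait under truncation
#' selection on the index I = b'y is
#' \deqn{\Phi = i \, b'G / \sqrt{b'Pb}}
#' with selection intensity i, genetic covariance G and phenotypic
#' covariance P = G + E. Traits with a zero weight still change through
#' their genetic covariances with the weighted traits (correlated
#' response).
#'
#' @param intensity Selection intensity i (standardized selection
#'   differential, e.g. cumulated over a planning horizon).
#' @param spec An [IndexSpec-class]; coefficient names must match the
#'   covariance trait labels.
#' @param cov A [TraitCovariances-class].
#' @return Named gain vector in trait units.
#' @examples
#' expectedGains(3.02, pd19IndexWeights(), ilTraitCovariances())
#' @export
expectedGains <- function(intensity, spec, cov) {
  b <- indexCoefficients(spec)
  tr <- traitNames(cov)
  stopifnot(all(names(b) %in% tr))
  b <- b[tr]
  G <- genCov(cov)
  bPb <- drop(t(b) %*% phenCov(cov) %*% b)
  if (bPb <= 0) stop("index has non-positive phenotypic variance (b'Pb <= 0)")
  intensity * drop(b %*% G) / sqrt(bPb)
}

#' Total expected economic gain
#'
#' TEG = Phi'b: the gain vector priced at the index weights.
#'
#' @param gains Named gain vector (as from [expectedGains()] or a
#'   realized-trend vector).
#' @param spec An [IndexSpec-class].
#' @return Scalar economic gain in index units.
#' @export
totalGain <- function(gains, spec) {
  b <- indexCoefficients(spec)
  if (length(gains) != length(b)) stop("gain vector length mismatch")
  if (!is.null(names(gains))) gains <- gains[names(b)]
  sum(gains * b)
}

#' Calibrate the selection intensity against a realized gain
#'
#' The intensity cumulated over the four selection pathways is only
#' known approximately, so it is backed out of the realized total
#' economic gain: i = TEG_realized * sqrt(b'Pb) / (b'Gb). The round
#' trip totalGain(expectedGains(i, ...)) recovers TEG_realized exactly.
#'
#' @param spec An [IndexSpec-class].
#' @param cov A [TraitCovariances-class].
#' @param realizedTeg Realized total economic gain.
#' @return The implied selection intensity.
#' @examples
#' calibrateIntensity(pd19IndexWeights(), ilTraitCovariances(), 1300.7)
#' @export
calibrateIntensity <- function(spec, cov, realizedTeg) {
  b <- indexCoefficients(spec)[traitNames(cov)]
  bGb <- drop(t(b) %*% genCov(cov) %*% b)
  if (bGb == 0) stop("index has zero genetic variance (b'Gb = 0)")
  bPb <- drop(t(b) %*% phenCov(cov) %*% b)
  realizedTeg * sqrt(bPb) / bGb
}

#' Standardized realized-minus-expected discrepancies
#'
#' d_j = s_j (realized_j - expected_j) / g_j, where s_j is -1 for
#' traits whose favorable direction is negative (so a positive value
#' always means the realized gain in the desired direction exceeded the
#' expected gain) and g_j is the genetic SD.
#'
#' @param expected,realized Named gain vectors.
#' @param g Named genetic SDs.
#' @param spec An [IndexSpec-class] supplying the favorable directions.
#' @return Named standardized discrepancies.
#' @export
discrepancyTable <- function(expected, realized, g, spec) {
  s <- favorableSign(spec)
  nm <- names(s)
  if (any(g[nm] == 0)) stop("zero genetic SD makes the discrepancy undefined")
  (s * (realized[nm] - expected[nm]) / g[nm])[nm]
}

#' Full gain report for an index
#'
#' Assembles the per-trait summary of index selection: genetic SD,
#' index fraction, expected gain at the given (or calibrated)
#' intensity, realized gain and the standardized discrepancy, plus the
#' expected and realized total economic gain.
#'
#' @param spec An [IndexSpec-class].
#' @param cov A [TraitCovariances-class].
#' @param realized Named realized gain vector (same traits).
#' @param realizedSe Optional named SEs of the realized gains.
#' @param intensity Selection intensity; ignored when `calibrate` is
#'   TRUE.
#' @param calibrate When TRUE (default) the intensity is calibrated so
#'   the expected total gain equals the realized one.
#' @return A data.frame (one row per trait) with attributes
#'   `"intensity"` and `"teg"` (expected and realized totals).
#' @export
gainReport <- function(spec, cov, realized, realizedSe = NULL,
                       intensity = NULL, calibrate = is.null(intensity)) {
  b <- indexCoefficients(spec)
  g <- geneticSd(cov)[names(b)]
  realized <- realized[names(b)]
  if (calibrate)
    intensity <- calibrateIntensity(spec, cov, totalGain(realized, spec))
  phi <- expectedGains(intensity, spec, cov)[names(b)]
  out <- data.frame(
    trait = names(b), geneticSd = g,
    fraction = indexFractions(spec, g),
    expected = phi, realized = realized,
    realizedSe = if (is.null(realizedSe)) NA_real_ else realizedSe[names(b)],
    discrepancy = discrepancyTable(phi, realized, g, spec),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "intensity") <- intensity
  attr(out, "teg") <- c(expected = totalGain(phi, spec),
                        realized = totalGain(realized, spec))
  out
}
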