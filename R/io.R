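## Plain-text interchange for phenotypes, inseminations and matrices.

#' Phenotype / insemination CSV interchange
#'
#' Long phenotype files carry animal, parity, trait, value, hys (and
#' optionally fresh date); insemination files carry animal, parity,
#' service, date, outcome.
#'
#' @param x Data frame to write.
#' @param file Path.
#' @export
writePhenotypesCsv <- function(x, file) {
  write.csv(x, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writePhenotypesCsv
#' @export
readPhenotypesCsv <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE,
                 colClasses = c(animal = "character"))
  if ("fresh" %in% colnames(df)) df$fresh <- as.Date(df$fresh)
  df
}

#' @rdname writePhenotypesCsv
#' @export
writeInseminationsCsv <- function(x, file) {
  write.csv(x, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writePhenotypesCsv
#' @export
readInseminationsCsv <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE,
                 colClasses = c(animal = "character"))
  df$date <- as.Date(df$date)
  df
}

#' Labeled matrix TSV interchange
#'
#' Writes a numeric matrix (e.g. index weights, G or E) with row labels
#' in the first column and a header of column labels; the reader
#' restores the matrix.
#'
#' @param m Numeric matrix with dimnames.
#' @param file Path.
#' @export
writeMatrixTsv <- function(m, file) {
  df <- data.frame(label = rownames(m) %||% seq_len(nrow(m)),
                   as.data.frame(m), check.names = FALSE)
  write.table(df, file, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(file)
}

#' @rdname writeMatrixTsv
#' @export
readMatrixTsv <- function(file) {
  df <- read.table(file, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
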