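#' Read a marker dosage matrix
#'
#' Two dialects are supported.  `"csv"`: first column `Line`, then one
#' column per marker holding additive dosages coded 0/1/2 (missing as `NA`
#' or empty).  `"plink_raw"`: the whitespace-delimited PLINK `--recode A`
#' export, whose six leading metadata columns (FID IID PAT MAT SEX
#' PHENOTYPE) are dropped; line identifiers are taken from IID.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"plink_raw"`.
#' @param strict when TRUE (default) any non-missing dosage outside
#'   \{0, 1, 2\} is an error; when FALSE fractional dosages (e.g. from
#'   upstream imputation) are allowed.
#' @return numeric J x p matrix with line ids as rownames and marker ids
#'   as colnames.
#' @export
read_markers <- function(path, dialect = c("csv", "plink_raw"), strict = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("marker file not found: ", path)
  if (dialect == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), check.names = FALSE)
    if (ncol(df) < 2L) stop("marker CSV needs a Line column plus markers")
    ids <- as.character(df[[1L]])
    M <- as.matrix(df[, -1L, drop = FALSE])
  } else {
    df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""), check.names = FALSE)
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(meta %in% names(df)))
      stop("PLINK .raw file must carry columns ", paste(meta, collapse = " "))
    ids <- as.character(df$IID)
    M <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  }
  storage.mode(M) <- "double"
  if (anyDuplicated(ids)) stop("duplicate line identifiers in ", path)
  rownames(M) <- ids
  if (ncol(M) < 1L) stop("no marker columns in ", path)
  if (strict) {
    bad <- which(!is.na(M) & !(M %in% c(0, 1, 2)), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("dosage %g outside {0,1,2} at line '%s', marker '%s'",
                   M[bad[1L, 1L], bad[1L, 2L]], rownames(M)[bad[1L, 1L]],
                   colnames(M)[bad[1L, 2L]]))
  }
  M
}

#' Write a marker matrix as CSV
#' @param markers J x p dosage matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path) {
  df <- data.frame(Line = rownames(markers), markers, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a square genomic relationship matrix
#'
#' Expects a CSV whose first row and first column hold the same line
#' identifiers in the same order.
#'
#' @param path CSV path.
#' @return J x J numeric matrix with line ids as dimnames.
#' @export
read_grm <- function(path) {
  if (!file.exists(path)) stop("GRM file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1L]])
  G <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(G) <- "double"
  if (nrow(G) != ncol(G)) stop("GRM is not square: ", path)
  if (!identical(ids, colnames(G)))
    stop("GRM row and column identifiers disagree: ", path)
  dimnames(G) <- list(ids, ids)
  G
}

#' Write a genomic relationship matrix as CSV
#' @param G square matrix with line-id dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grm <- function(G, path) {
  df <- data.frame(Line = rownames(G), G, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
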