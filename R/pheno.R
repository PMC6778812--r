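#' Multi-trait multi-environment phenotype grid
#'
#' A `pheno_grid` holds phenotypic records for J lines evaluated in I
#' environments on L traits as a complete J x I grid of cells.  Cells are
#' stored in a fixed canonical order -- environment-major, lines nested
#' within environment -- which is the stacking used to build all design
#' matrices downstream.  Cells for which no record exists carry `NA`.
#'
#' @param records data.frame with columns `Line`, `Env` and one numeric
#'   column per trait.  Each (line, environment) pair may appear at most
#'   once; pairs absent from `records` become missing cells.
#' @param lines,envs optional character vectors fixing the line and
#'   environment sets (and their order).  Defaults to the sorted unique
#'   values found in `records`.
#'
#' @return An object of class `pheno_grid`: a list with elements
#'   `lines` (J ids), `envs` (I ids), `traits` (L names), and `Y`, an
#'   N x L numeric matrix (N = J*I) in canonical cell order with `NA`
#'   for unobserved cells.
#' @seealso [read_phenotypes()], [cell_index()], [simulate_phenotypes()]
#' @export
phenotype_grid <- function(records, lines = NULL, envs = NULL) {
  stopifnot(is.data.frame(records))
  nm <- names(records)
  if (!all(c("Line", "Env") %in% nm))
    stop("phenotype records need 'Line' and 'Env' columns")
  traits <- setdiff(nm, c("Line", "Env"))
  if (length(traits) < 1L) stop("at least one trait column is required")
  if (anyDuplicated(traits)) stop("trait names must be unique")
  rec_line <- as.character(records$Line)
  rec_env <- as.character(records$Env)
  if (is.null(lines)) lines <- sort(unique(rec_line))
  if (is.null(envs)) envs <- sort(unique(rec_env))
  lines <- as.character(lines)
  envs <- as.character(envs)
  if (anyDuplicated(lines)) stop("line identifiers must be unique")
  if (anyDuplicated(envs)) stop("environment identifiers must be unique")
  if (!all(rec_line %in% lines)) stop("records contain lines not in 'lines'")
  if (!all(rec_env %in% envs)) stop("records contain environments not in 'envs'")
  J <- length(lines); I <- length(envs); N <- J * I
  key <- paste(rec_env, rec_line, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    d <- strsplit(d, "\r", fixed = TRUE)[[1L]]
    stop(sprintf("duplicate cell: line '%s' in environment '%s'", d[2L], d[1L]))
  }
  idx <- (match(rec_env, envs) - 1L) * J + match(rec_line, lines)
  Y <- matrix(NA_real_, N, length(traits), dimnames = list(NULL, traits))
  for (tr in traits) {
    v <- records[[tr]]
    if (!is.numeric(v))
      stop(sprintf("trait column '%s' is not numeric", tr))
    Y[idx, tr] <- v
  }
  structure(list(lines = lines, envs = envs, traits = traits, Y = Y),
            class = "pheno_grid")
}

#' Canonical cell indices of (line, environment) pairs
#'
#' Cells are ordered environment-major: cell index of line j in environment
#' i is (i-1)*J + j, with i and j positions in `pheno$envs` and
#' `pheno$lines`.
#'
#' @param pheno a [phenotype_grid()].
#' @param env,line character vectors (recycled to common length).
#' @return integer vector of row indices into `pheno$Y`.
#' @export
cell_index <- function(pheno, env, line) {
  i <- match(as.character(env), pheno$envs)
  j <- match(as.character(line), pheno$lines)
  if (anyNA(i)) stop("unknown environment: ", env[which(is.na(i))[1L]])
  if (anyNA(j)) stop("unknown line: ", line[which(is.na(j))[1L]])
  (i - 1L) * length(pheno$lines) + j
}

#' All cells of a phenotype grid as a data.frame
#'
#' @param x a `pheno_grid`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns `Env`, `Line` (canonical cell order)
#'   and one column per trait.
#' @export
as.data.frame.pheno_grid <- function(x, row.names = NULL, optional = FALSE, ...) {
  J <- length(x$lines); I <- length(x$envs)
  out <- data.frame(Env = rep(x$envs, each = J),
                    Line = rep(x$lines, times = I),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(x$Y))
}

#' @export
print.pheno_grid <- function(x, ...) {
  J <- length(x$lines); I <- length(x$envs); L <- length(x$traits)
  cat(sprintf("pheno_grid: %d lines x %d environments (%d cells), %d trait%s\n",
              J, I, J * I, L, if (L == 1L) "" else "s"))
  cat("traits:", paste(x$traits, collapse = ", "), "\n")
  nmiss <- colSums(is.na(x$Y))
  if (any(nmiss > 0))
    cat("missing cells per trait:", paste(sprintf("%s=%d", x$traits, nmiss),
                                          collapse = ", "), "\n")
  invisible(x)
}

ncells <- function(pheno) length(pheno$lines) * length(pheno$envs)

#' Read a long-format phenotype table
#'
#' Expects a CSV with columns `Line`, `Env` and one numeric column per
#' trait (one row per observed cell).  The grid is completed: (line, env)
#' pairs without a row become missing cells.  Empty strings and `NA` are
#' both accepted as the missing-value token.
#'
#' @param path CSV file path.
#' @param dialect only `"long"` is supported.
#' @return a [phenotype_grid()].
#' @export
read_phenotypes <- function(path, dialect = "long") {
  dialect <- match.arg(dialect, c("long", "wide"))
  if (dialect == "wide")
    stop("the wide phenotype dialect is not supported; use long format")
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""), check.names = FALSE)
  if (!all(c("Line", "Env") %in% names(df)))
    stop("phenotype file must have 'Line' and 'Env' columns: ", path)
  traits <- setdiff(names(df), c("Line", "Env"))
  for (tr in traits) {
    v <- df[[tr]]
    if (is.character(v)) {
      bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' for trait '%s' at data row %d",
                     v[bad[1L]], tr, bad[1L]))
      df[[tr]] <- as.numeric(v)
    }
  }
  phenotype_grid(df)
}

#' Write a phenotype grid as a long CSV
#'
#' Emits one row per cell with at least one observed trait; fully missing
#' cells are omitted so that `read_phenotypes()` restores the same mask.
#' Missing trait values within an emitted row are written as `NA`.
#'
#' @param pheno a `pheno_grid`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  df <- as.data.frame(pheno)
  keep <- rowSums(!is.na(pheno$Y)) > 0
  utils::write.csv(df[keep, , drop = FALSE], path, row.names = FALSE, na = "NA")
  invisible(path)
}
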