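#' Marker quality control
#'
#' Applies, in this order, three independent per-marker filters computed on
#' the original calls: (1) missingness -- drop markers whose fraction of
#' missing calls exceeds `max_missing`; (2) minor allele frequency -- drop
#' markers whose MAF is less than *or equal to* `min_maf`, where MAF =
#' min(p, 1-p) with p = mean(non-missing dosage)/2; (3) heterozygosity
#' (optional) -- drop markers whose fraction of heterozygous (dosage 1)
#' non-missing calls exceeds `max_het`.
#'
#' @param markers J x p dosage matrix (0/1/2 with `NA`).
#' @param max_missing maximum tolerated missing fraction, in \[0, 1\].
#' @param min_maf MAF removal threshold in \[0, 0.5\]; markers at or below
#'   it are removed.
#' @param max_het maximum heterozygous fraction, or `NULL` to disable.
#' @return list with `markers` (the surviving columns) and `log`, a
#'   data.frame with one row per removed marker (`marker`, `rule`,
#'   `value`).
#' @export
filter_markers <- function(markers, max_missing = 0.8, min_maf = 0.05,
                           max_het = NULL) {
  stopifnot(is.matrix(markers), ncol(markers) >= 1L)
  if (max_missing < 0 || max_missing > 1) stop("max_missing must be in [0,1]")
  if (min_maf < 0 || min_maf > 0.5) stop("min_maf must be in [0,0.5]")
  if (!is.null(max_het) && (max_het < 0 || max_het > 1))
    stop("max_het must be in [0,1]")
  miss <- colMeans(is.na(markers))
  p_hat <- colMeans(markers, na.rm = TRUE) / 2
  maf <- pmin(p_hat, 1 - p_hat)
  het <- colMeans(markers == 1, na.rm = TRUE)
  rule <- rep(NA_character_, ncol(markers))
  val <- rep(NA_real_, ncol(markers))
  # independent passes over the original calls, precedence miss > maf > het
  sel_miss <- miss > max_missing
  sel_maf <- !sel_miss & (is.nan(maf) | maf <= min_maf)
  rule[sel_miss] <- "missingness"; val[sel_miss] <- miss[sel_miss]
  rule[sel_maf] <- "maf"; val[sel_maf] <- maf[sel_maf]
  if (!is.null(max_het)) {
    sel_het <- !sel_miss & !sel_maf & het > max_het
    rule[sel_het] <- "heterozygosity"; val[sel_het] <- het[sel_het]
  }
  removed <- !is.na(rule)
  if (all(removed)) stop("no markers survive QC")
  log <- data.frame(marker = colnames(markers)[removed],
                    rule = rule[removed], value = val[removed],
                    stringsAsFactors = FALSE)
  list(markers = markers[, !removed, drop = FALSE], log = log)
}

#' Mean imputation of missing marker dosages
#'
#' Replaces each missing call by the column mean of the non-missing calls
#' for that marker.  Non-missing entries are unchanged.
#'
#' @param markers J x p dosage matrix.
#' @param method only `"column_mean"`.
#' @return complete J x p matrix.
#' @export
impute_markers <- function(markers, method = "column_mean") {
  method <- match.arg(method, "column_mean")
  if (!anyNA(markers)) return(markers)
  mu <- colMeans(markers, na.rm = TRUE)
  empty <- which(is.nan(mu))
  if (length(empty))
    stop("marker '", colnames(markers)[empty[1L]],
         "' has no non-missing calls; run filter_markers first")
  idx <- which(is.na(markers), arr.ind = TRUE)
  markers[idx] <- mu[idx[, 2L]]
  markers
}

#' Genomic relationship matrix G = W W' / p
#'
#' Builds the marker-based relationship kernel by cross-multiplying the
#' (by default column-centered) dosage matrix and dividing by the number
#' of markers.  Centering removes dependence on arbitrary allele labeling;
#' setting `center = FALSE` uses the raw dosages.
#'
#' @param markers complete J x p dosage matrix (no missing values).
#' @param center center each marker column at its mean before the
#'   cross-product (default TRUE).
#' @return J x J symmetric matrix with line ids as dimnames.
#' @export
compute_grm <- function(markers, center = TRUE) {
  stopifnot(is.matrix(markers))
  if (ncol(markers) < 1L) stop("no markers")
  if (anyNA(markers)) stop("markers contain missing values; impute first")
  W <- if (center) sweep(markers, 2L, colMeans(markers), "-") else markers
  G <- tcrossprod(W) / ncol(markers)
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(markers), rownames(markers))
  G
}

#' Eigendecomposition of a relationship kernel
#'
#' Symmetric eigendecomposition with a relative floor: components whose
#' eigenvalue falls below `tol` times the largest eigenvalue are dropped,
#' giving a rank-r orthonormal basis in which random effects with
#' covariance proportional to `G` are sampled.  Eigenvalues below
#' `-tol * max` (beyond numerical jitter) are an error.
#'
#' @param G square symmetric PSD matrix.
#' @param tol relative eigenvalue floor (default 1e-8).
#' @return list with `vectors` (J x r), `values` (r, descending), `rank`.
#' @export
kernel_eigen <- function(G, tol = 1e-8) {
  stopifnot(is.matrix(G), nrow(G) == ncol(G))
  if (max(abs(G - t(G))) > 1e-8 * max(1, max(abs(G))))
    stop("kernel is not symmetric")
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  lmax <- max(e$values, 0)
  if (min(e$values) < -tol * max(lmax, .Machine$double.eps))
    stop("kernel is not positive semi-definite (min eigenvalue ",
         format(min(e$values)), ")")
  keep <- e$values > tol * lmax
  if (!any(keep)) stop("kernel has no usable eigenvalues")
  list(vectors = e$vectors[, keep, drop = FALSE],
       values = e$values[keep], rank = sum(keep))
}
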