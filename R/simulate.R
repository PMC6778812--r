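#' Simulate a biallelic marker dosage matrix
#'
#' Each marker gets an allele frequency drawn uniformly from `maf_range`;
#' dosages are then independent Binomial(2, freq) across lines (no
#' linkage disequilibrium, no population structure, no missingness).
#'
#' @param J number of lines (>= 2).
#' @param p number of markers (>= 1).
#' @param maf_range allele-frequency interval, within (0, 0.5\].
#' @param seed integer seed.
#' @return J x p dosage matrix with line ids `L1..LJ` and marker ids
#'   `M1..Mp`.
#' @export
simulate_markers <- function(J, p, maf_range = c(0.05, 0.5), seed = 1L) {
  if (J < 2L) stop("need at least 2 lines")
  if (p < 1L) stop("need at least 1 marker")
  if (maf_range[1L] <= 0 || maf_range[2L] > 0.5 ||
      maf_range[1L] > maf_range[2L])
    stop("maf_range must lie within (0, 0.5]")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  freq <- stats::runif(p, maf_range[1L], maf_range[2L])
  M <- vapply(freq, function(f) stats::rbinom(J, 2L, f), numeric(J))
  dimnames(M) <- list(paste0("L", seq_len(J)), paste0("M", seq_len(p)))
  M
}

#' Inject missing calls into a marker matrix
#'
#' @param markers J x p dosage matrix.
#' @param rate fraction of entries set to `NA`.
#' @param seed integer seed.
#' @return matrix with missing entries.
#' @export
sprinkle_missing <- function(markers, rate = 0.05, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0,1)")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  n <- length(markers)
  idx <- sample.int(n, round(rate * n))
  markers[idx] <- NA_real_
  markers
}

# lower-triangular factor with a small relative jitter for PSD kernels
chol_psd <- function(S, jitter = 1e-8) {
  lmax <- max(diag(S), .Machine$double.eps)
  t(chol(S + diag(jitter * lmax, nrow(S))))
}

#' Simulate multi-trait multi-environment phenotypes with known truth
#'
#' Draws from the matrix-variate generative model
#' \deqn{Y = X \beta + Z_1 b_1 + Z_2 b_2 + E}
#' where Y is N x L (N = J*I cells, canonical environment-major order),
#' b1 ~ MN(0, G, Sigma_t) are genotype-by-trait effects, b2 ~ MN(0,
#' ge_scale * Sigma_E kron G, Sigma_t) are genotype-by-environment-by-
#' trait effects, and the rows of E are iid N(0, Re).  With L = 1,
#' Sigma_t = sigma2_g, Sigma_E = I and Re = sigma2_e this reduces exactly
#' to the single-trait G x E model fitted by [gblup_ge()].
#'
#' @param markers J x p complete dosage matrix; the kernel is
#'   `compute_grm(markers)`.
#' @param beta I x L matrix of environment-by-trait means.
#' @param Sigma_t L x L genetic trait covariance (positive definite).
#' @param Sigma_E I x I environment covariance of the interaction term.
#' @param Re L x L residual trait covariance.
#' @param ge_scale scalar multiplier of the interaction covariance.
#' @param seed integer seed.
#' @return list of class `sim_bundle`: `markers`, `grm`, `pheno` (a
#'   [phenotype_grid()]) and `truth` (all drawn effects plus the
#'   generating parameters).
#' @export
simulate_phenotypes <- function(markers, beta, Sigma_t, Sigma_E, Re,
                                ge_scale = 1, seed = 1L) {
  J <- nrow(markers)
  I <- nrow(Sigma_E); L <- nrow(Sigma_t)
  beta <- as.matrix(beta)
  if (!all(dim(beta) == c(I, L)))
    stop("beta must be I x L to match Sigma_E and Sigma_t")
  if (!isTRUE(all.equal(Sigma_t, t(Sigma_t))) ||
      any(eigen(Sigma_t, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("Sigma_t must be symmetric positive definite")
  if (any(eigen(Sigma_E, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("Sigma_E must be positive definite")
  if (any(eigen(Re, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("Re must be positive definite")
  if (ge_scale < 0) stop("ge_scale must be non-negative")

  G <- compute_grm(markers)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  Lg <- chol_psd(G)
  Lt <- chol_psd(Sigma_t)
  Le <- chol_psd(Sigma_E)
  Lr <- chol_psd(Re)

  # b1 ~ MN(0, G, Sigma_t):  Lg Z Lt'
  b1 <- Lg %*% matrix(stats::rnorm(J * L), J, L) %*% t(Lt)
  # b2 ~ MN(0, ge_scale * Sigma_E kron G, Sigma_t):
  # chol(Sigma_E kron G) = chol(Sigma_E) kron chol(G) applied blockwise
  Zb <- matrix(stats::rnorm(I * J * L), I * J, L)
  b2 <- matrix(0, I * J, L)
  for (i in seq_len(I)) {
    rows_i <- ((i - 1L) * J + 1L):(i * J)
    acc <- matrix(0, J, L)
    for (k in seq_len(I)) {
      if (Le[i, k] != 0)
        acc <- acc + Le[i, k] *
          (Lg %*% Zb[((k - 1L) * J + 1L):(k * J), , drop = FALSE])
    }
    b2[rows_i, ] <- sqrt(ge_scale) * acc %*% t(Lt)
  }
  E <- matrix(stats::rnorm(I * J * L), I * J, L) %*% t(Lr)

  lines <- rownames(markers)
  envs <- paste0("E", seq_len(I))
  traits <- if (!is.null(colnames(beta))) colnames(beta)
  else paste0("T", seq_len(L))
  Xb <- beta[rep(seq_len(I), each = J), , drop = FALSE]
  Z1b1 <- b1[rep(seq_len(J), times = I), , drop = FALSE]
  Y <- Xb + Z1b1 + b2 + E
  colnames(Y) <- traits

  pheno <- structure(list(lines = lines, envs = envs, traits = traits,
                          Y = Y), class = "pheno_grid")
  truth <- list(beta = beta, Sigma_t = Sigma_t, Sigma_E = Sigma_E, Re = Re,
                ge_scale = ge_scale, b1 = b1, b2 = b2, E = E,
                seed = as.integer(seed))
  structure(list(markers = markers, grm = G, pheno = pheno, truth = truth),
            class = "sim_bundle")
}

#' Simulate a standard multi-trait scenario
#'
#' Convenience wrapper around [simulate_markers()] and
#' [simulate_phenotypes()] with the package's reference conditions:
#' genetic trait covariance with unit variances and a common correlation
#' `g_cor`, interaction covariance `sigma2_ge * I`, uncorrelated
#' residuals with variance `sigma2_e`, and environment means near
#' `mu` so relative errors (MAAPE) are well defined.
#'
#' @param J,I,L,p lines, environments, traits, markers.
#' @param g_cor genetic correlation between every trait pair.
#' @param sigma2_g,sigma2_ge,sigma2_e genomic, interaction and residual
#'   variances per trait.
#' @param mu grand mean of every trait (environment means are spread
#'   +/- 1 around it).
#' @param maf_range marker allele-frequency range.
#' @param seed integer seed.
#' @return a `sim_bundle` (see [simulate_phenotypes()]).
#' @export
simulate_scenario <- function(J = 300L, I = 3L, L = 3L, p = 1000L,
                              g_cor = 0.5, sigma2_g = 1, sigma2_ge = 0.5,
                              sigma2_e = 0.5, mu = 10,
                              maf_range = c(0.05, 0.5), seed = 1L) {
  if (abs(g_cor) >= 1) stop("g_cor must be in (-1, 1)")
  markers <- simulate_markers(J, p, maf_range, seed = seed)
  Sigma_t <- sigma2_g * ((1 - g_cor) * diag(L) + g_cor)
  Sigma_E <- diag(I)
  Re <- sigma2_e * diag(L)
  env_shift <- if (I > 1L) seq(-1, 1, length.out = I) else 0
  beta <- matrix(mu, I, L) + env_shift
  simulate_phenotypes(markers, beta, Sigma_t, Sigma_E, Re,
                      ge_scale = sigma2_ge, seed = child_seed(seed, 17L))
}

#' Training mask for a random incomplete-trial scenario
#'
#' Draws one cross-validation partition (see [make_partitions()]) and
#' returns its training cells.
#'
#' @param pheno a [phenotype_grid()].
#' @param p_testing testing fraction in (0, 1).
#' @param seed integer seed.
#' @return integer vector of training cell indices.
#' @export
mask_for_scenario <- function(pheno, p_testing = 0.2, seed = 1L) {
  make_partitions(pheno, p_testing, 1L, seed)[[1L]]$train
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("simulated multi-trait multi-environment bundle\n")
  cat(sprintf("  %d lines x %d markers; %d environments; %d trait(s)\n",
              nrow(x$markers), ncol(x$markers), length(x$pheno$envs),
              length(x$pheno$traits)))
  invisible(x)
}
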