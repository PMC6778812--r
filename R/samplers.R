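#' Draw from a scaled inverse chi-square distribution
#'
#' Parameterized as S / chisq(v): density proportional to
#' (x)^-(v/2+1) exp(-S/(2x)).  Under this convention the prior mode is
#' S/(v+2) and the prior mean S/(v-2) (for v > 2), which is why variance
#' priors are elicited as S = Var(y) * R2 * (v+2): the prior mode then
#' sits at the targeted share R2 of the phenotypic variance.
#'
#' @param n number of draws.
#' @param df degrees of freedom v > 0.
#' @param scale scale S > 0.
#' @return numeric vector of positive draws.
#' @export
rscaled_inv_chisq <- function(n, df, scale) {
  if (df <= 0) stop("df must be positive")
  if (scale <= 0) stop("scale must be positive")
  scale / stats::rchisq(n, df)
}

#' Conjugate variance-component update
#'
#' Gibbs full-conditional draw for a variance component with scaled
#' inverse chi-square prior (v, S) given currently sampled effects:
#' (S + q) / chisq(v + k) with q the prior-metric quadratic form of the
#' effects and k their effective dimension.  With no effects (k = 0) this
#' is a pure prior draw.
#'
#' @param effects numeric vector of current effect values (possibly
#'   length 0).
#' @param df,scale prior degrees of freedom and scale.
#' @param metric precision metric for the quadratic form: `NULL`
#'   (identity), a vector (diagonal), or a square matrix.
#' @return one positive draw.
#' @export
update_variance <- function(effects, df, scale, metric = NULL) {
  k <- length(effects)
  if (k == 0L) return(rscaled_inv_chisq(1L, df, scale))
  q <- if (is.null(metric)) sum(effects^2)
  else if (is.matrix(metric)) drop(crossprod(effects, metric %*% effects))
  else sum(effects^2 * metric)
  if (q < 0) stop("negative quadratic form; metric is not PSD")
  (scale + q) / stats::rchisq(1L, df + k)
}

#' Exact Gaussian block draw for a conjugate full conditional
#'
#' Draws from N(C^-1 r, C^-1) with C = XtX / error_var + prior precision
#' and r = Xty / error_var -- the standard mixed-model full conditional of
#' a coefficient block with Gaussian prior.  Uses a Cholesky factorization
#' of C.
#'
#' @param XtX k x k cross-product of the block's design columns.
#' @param Xty length-k cross-product with the working residual.
#' @param prior_prec prior precision: scalar, length-k vector (diagonal)
#'   or k x k matrix.
#' @param error_var residual variance.
#' @return length-k draw.
#' @export
draw_gaussian_block <- function(XtX, Xty, prior_prec, error_var) {
  if (error_var <= 0) stop("error_var must be positive")
  k <- length(Xty)
  C <- XtX / error_var
  if (is.matrix(prior_prec)) C <- C + prior_prec
  else C <- C + diag(rep_len(prior_prec, k), k)
  R <- chol(C)
  mu <- backsolve(R, backsolve(R, Xty / error_var, transpose = TRUE))
  drop(mu + backsolve(R, stats::rnorm(k)))
}

# Whitened eigenbasis sampler for a kernel-structured random-effect block.
#
# The full conditional of coefficients a (prior N(0, s2_u * D), D diagonal
# from the kernel eigendecomposition) given a likelihood cross-product
# A = Uᵀ Zᵀ Z U that is *fixed across iterations* is N(C^-1 u, C^-1) with
# C = A / s2_e + D^-1 / s2_u.  Writing B = D^(1/2) A D^(1/2) = V L Vᵀ and
# W = D^(1/2) V (precomputed once), C^-1 = W diag(1/(L/s2_e + 1/s2_u)) Wᵀ,
# so each iteration needs only two r x r matrix-vector products and no
# factorization.
make_block_sampler <- function(A, d) {
  sd_half <- sqrt(d)
  B <- sd_half * t(sd_half * t(A))      # D^{1/2} A D^{1/2}
  eB <- eigen((B + t(B)) / 2, symmetric = TRUE)
  W <- sd_half * eB$vectors
  list(W = W, lambda = pmax(eB$values, 0), d = d)
}

# u: Uᵀ Zᵀ (working residual); returns a draw of the r eigen-coefficients.
block_draw <- function(bs, u, s2_u, s2_e) {
  prec <- bs$lambda / s2_e + 1 / s2_u
  t1 <- crossprod(bs$W, u / s2_e)
  drop(bs$W %*% (t1 / prec + stats::rnorm(length(prec)) / sqrt(prec)))
}
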