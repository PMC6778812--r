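#' MCMC chain settings
#'
#' @param niter total Gibbs iterations.
#' @param burnin iterations discarded before retention; must be < niter.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @return list of class `mcmc_control`.
#' @export
mcmc_control <- function(niter = 10000L, burnin = 5000L, thin = 5L) {
  niter <- as.integer(niter); burnin <- as.integer(burnin)
  thin <- as.integer(thin)
  if (burnin >= niter) stop("burnin must be smaller than niter")
  if (thin < 1L) stop("thin must be >= 1")
  structure(list(niter = niter, burnin = burnin, thin = thin),
            class = "mcmc_control")
}

resolve_trait <- function(pheno, trait) {
  if (is.numeric(trait)) trait <- pheno$traits[trait]
  if (is.na(trait) || !trait %in% pheno$traits)
    stop("unknown trait: ", trait)
  trait
}

resolve_train <- function(pheno, train) {
  N <- ncells(pheno)
  if (is.null(train)) return(seq_len(N))
  if (is.logical(train)) {
    if (length(train) != N) stop("logical train mask must have length N")
    return(which(train))
  }
  train <- as.integer(train)
  if (any(train < 1L | train > N)) stop("train cell indices out of range")
  sort(unique(train))
}

#' Design matrices for the single-trait G x E model
#'
#' Builds, for the training records of one trait, the response vector and
#' the dense incidence matrices of the linear model
#' y = X beta + Z1 g + Z2 gE + e: `X` (n x I environments), `Z1` (n x J
#' lines) and `Z2` (n x I*J environment-by-line cells, canonical cell
#' order).  Intended for small problems and closed-form cross-checks; the
#' Gibbs sampler itself uses index vectors instead.
#'
#' @param pheno a [phenotype_grid()].
#' @param trait trait name or index.
#' @param train training cells: `NULL` (all), logical length-N mask or
#'   integer cell indices.  Records missing in `pheno` are always
#'   excluded.
#' @return list with `y`, `X`, `Z1`, `Z2`, and `cells` (the canonical
#'   indices of the training records).
#' @export
build_designs <- function(pheno, trait, train = NULL) {
  trait <- resolve_trait(pheno, trait)
  J <- length(pheno$lines); I <- length(pheno$envs)
  keep <- resolve_train(pheno, train)
  y_full <- pheno$Y[, trait]
  cells <- keep[!is.na(y_full[keep])]
  if (length(cells) < 1L) stop("no training records")
  env_idx <- (cells - 1L) %/% J + 1L
  line_idx <- (cells - 1L) %% J + 1L
  absent <- setdiff(seq_len(I), unique(env_idx))
  if (length(absent))
    stop("environment '", pheno$envs[absent[1L]],
         "' has no training records; its effect is unidentifiable")
  n <- length(cells)
  X <- matrix(0, n, I, dimnames = list(NULL, pheno$envs))
  X[cbind(seq_len(n), env_idx)] <- 1
  Z1 <- matrix(0, n, J, dimnames = list(NULL, pheno$lines))
  Z1[cbind(seq_len(n), line_idx)] <- 1
  Z2 <- matrix(0, n, I * J)
  Z2[cbind(seq_len(n), cells)] <- 1
  list(y = y_full[cells], X = X, Z1 = Z1, Z2 = Z2, cells = cells)
}

#' Bayesian GBLUP with genotype-by-environment interaction
#'
#' Fits, by Gibbs sampling, the single-trait model
#' \deqn{y_{ij} = E_i + g_j + gE_{ij} + e_{ij}}
#' with fixed environment effects E_i (Gaussian prior with variance 1e10),
#' genomic line effects g ~ N(0, sigma2_g * G), interaction effects
#' gE ~ N(0, sigma2_ge * I kron G) and residuals e ~ N(0, sigma2_e).
#' Variance components carry scaled inverse chi-square priors with scale
#' S = Var(y_train) * R2 * (df + 2), so the prior mode of each component
#' is its targeted share R2 of the phenotypic variance.
#'
#' Random-effect blocks are sampled exactly from their joint full
#' conditionals in a whitened eigenbasis of `G` precomputed once per fit,
#' so lines without training records receive draws through their kernel
#' correlation with trained lines.
#'
#' @param pheno a [phenotype_grid()].
#' @param trait trait name or index.
#' @param G genomic relationship matrix covering (at least) all lines of
#'   `pheno`, with line ids as dimnames.
#' @param train training cells as in [build_designs()]; all other cells
#'   are ignored by the likelihood and only ever predicted.
#' @param control an [mcmc_control()].
#' @param seed integer seed; the chain is reproducible given (data,
#'   priors, control, seed).
#' @param df_g,df_ge,df_e prior degrees of freedom (all 5 by default).
#' @param R2_g,R2_ge,R2_e targeted prior variance shares for the genomic,
#'   interaction and residual components (0.5, 0.25, 0.25).
#' @param fix_variances optional named vector/list with any of `g`, `ge`,
#'   `e`: variance components to freeze at the given values instead of
#'   sampling (used for conjugate-oracle checks).
#' @param eig optional precomputed [kernel_eigen()] of `G` restricted to
#'   `pheno$lines` (saves the decomposition when many fits share one G).
#' @return object of class `gblup_ge` with posterior means `beta` (per
#'   environment), `g` (per line), `ge` (J x I matrix), `yhat` (all N
#'   cells, canonical order), retained draws of `beta` and the variance
#'   components, and chain metadata.
#' @examples
#' sim <- simulate_scenario(J = 40, I = 2, L = 1, p = 120, seed = 1)
#' fit <- gblup_ge(sim$pheno, 1, sim$grm,
#'                 control = mcmc_control(600, 200, 2), seed = 1)
#' fit
#' @export
gblup_ge <- function(pheno, trait, G, train = NULL,
                     control = mcmc_control(), seed = 1L,
                     df_g = 5, df_ge = 5, df_e = 5,
                     R2_g = 0.5, R2_ge = 0.25, R2_e = 0.25,
                     fix_variances = NULL, eig = NULL) {
  trait <- resolve_trait(pheno, trait)
  J <- length(pheno$lines); I <- length(pheno$envs); N <- J * I
  if (is.null(rownames(G)) || !all(pheno$lines %in% rownames(G)))
    stop("G must have line ids as dimnames and cover all phenotyped lines")
  keep <- resolve_train(pheno, train)
  y_full <- pheno$Y[, trait]
  cells <- keep[!is.na(y_full[keep])]
  if (length(cells) < 2L) stop("need at least 2 training records")
  env_idx <- (cells - 1L) %/% J + 1L
  line_idx <- (cells - 1L) %% J + 1L
  absent <- setdiff(seq_len(I), unique(env_idx))
  if (length(absent))
    stop("environment '", pheno$envs[absent[1L]],
         "' has no training records; its effect is unidentifiable")
  y <- y_full[cells]
  n <- length(y)

  if (is.null(eig)) eig <- kernel_eigen(G[pheno$lines, pheno$lines])
  U <- eig$vectors; d <- eig$values; r <- eig$rank

  vary <- stats::var(y)
  if (vary <= 0) vary <- 1e-8   # degenerate constant response
  S_g <- vary * R2_g * (df_g + 2)
  S_ge <- vary * R2_ge * (df_ge + 2)
  S_e <- vary * R2_e * (df_e + 2)

  fixed <- function(nm) !is.null(fix_variances) && !is.null(fix_variances[[nm]])

  # per-line training counts and per-environment cell bookkeeping
  m_line <- tabulate(line_idx, J)
  bs_g <- make_block_sampler(crossprod(sqrt(m_line) * U), d)
  env_cells <- split(seq_len(n), factor(env_idx, levels = seq_len(I)))
  env_lines <- lapply(env_cells, function(ix) line_idx[ix])
  bs_ge <- lapply(seq_len(I), function(i) {
    li <- env_lines[[i]]
    make_block_sampler(crossprod(U[li, , drop = FALSE]), d)
  })
  n_env <- lengths(env_cells)

  set.seed(as.integer(seed) %% .Machine$integer.max)

  # initial state
  beta <- as.vector(rowsum(y, env_idx, reorder = TRUE)) / n_env
  g <- numeric(J)
  ge <- matrix(0, J, I)
  s2g <- if (fixed("g")) fix_variances[["g"]] else vary * R2_g
  s2ge <- if (fixed("ge")) fix_variances[["ge"]] else vary * R2_ge
  s2e <- if (fixed("e")) fix_variances[["e"]] else vary * R2_e

  ctl <- control
  kept <- (ctl$niter - ctl$burnin) %/% ctl$thin
  beta_draws <- matrix(NA_real_, kept, I, dimnames = list(NULL, pheno$envs))
  var_draws <- matrix(NA_real_, kept, 3L,
                      dimnames = list(NULL, c("sigma2_g", "sigma2_ge",
                                              "sigma2_e")))
  sum_beta <- numeric(I); sum_g <- numeric(J); sum_ge <- matrix(0, J, I)
  k_out <- 0L
  prior_prec_beta <- 1e-10

  for (it in seq_len(ctl$niter)) {
    ge_part <- ge[cbind(line_idx, env_idx)]
    # environment effects: independent scalar conditionals (X'X diagonal)
    e_beta <- y - g[line_idx] - ge_part
    sums <- as.vector(rowsum(e_beta, env_idx, reorder = TRUE))
    prec_b <- n_env / s2e + prior_prec_beta
    beta <- sums / s2e / prec_b + stats::rnorm(I) / sqrt(prec_b)

    # genomic main effects in the kernel eigenbasis
    e_g <- y - beta[env_idx] - ge_part
    s <- numeric(J)
    for (i in seq_len(I)) {
      ix <- env_cells[[i]]
      if (length(ix)) s[env_lines[[i]]] <- s[env_lines[[i]]] + e_g[ix]
    }
    a <- block_draw(bs_g, crossprod(U, s), s2g, s2e)
    g <- drop(U %*% a)

    # interaction effects, one kernel block per environment
    b <- matrix(0, r, I)
    for (i in seq_len(I)) {
      ix <- env_cells[[i]]
      s <- numeric(J)
      s[env_lines[[i]]] <- y[ix] - beta[i] - g[env_lines[[i]]]
      b[, i] <- block_draw(bs_ge[[i]], crossprod(U, s), s2ge, s2e)
      ge[, i] <- U %*% b[, i]
    }

    # variance components
    if (!fixed("g")) s2g <- (S_g + sum(a^2 / d)) / stats::rchisq(1L, df_g + r)
    if (!fixed("ge"))
      s2ge <- (S_ge + sum(b^2 / d)) / stats::rchisq(1L, df_ge + I * r)
    resid <- y - beta[env_idx] - g[line_idx] - ge[cbind(line_idx, env_idx)]
    if (!fixed("e")) s2e <- (S_e + sum(resid^2)) / stats::rchisq(1L, df_e + n)

    if (it > ctl$burnin && (it - ctl$burnin) %% ctl$thin == 0L) {
      k_out <- k_out + 1L
      beta_draws[k_out, ] <- beta
      var_draws[k_out, ] <- c(s2g, s2ge, s2e)
      sum_beta <- sum_beta + beta
      sum_g <- sum_g + g
      sum_ge <- sum_ge + ge
    }
  }

  beta_hat <- sum_beta / k_out
  g_hat <- sum_g / k_out
  ge_hat <- sum_ge / k_out
  names(beta_hat) <- pheno$envs
  names(g_hat) <- pheno$lines
  dimnames(ge_hat) <- list(pheno$lines, pheno$envs)
  yhat <- unname(rep(beta_hat, each = J) + rep(g_hat, times = I)) +
    as.vector(ge_hat)

  structure(list(
    trait = trait, lines = pheno$lines, envs = pheno$envs,
    beta = beta_hat, g = g_hat, ge = ge_hat, yhat = yhat,
    variances = colMeans(var_draws),
    draws = list(beta = beta_draws, variances = var_draws),
    prior = list(df = c(g = df_g, ge = df_ge, e = df_e),
                 scale = c(g = S_g, ge = S_ge, e = S_e),
                 R2 = c(g = R2_g, ge = R2_ge, e = R2_e), var_y = vary),
    chain = list(niter = ctl$niter, burnin = ctl$burnin, thin = ctl$thin,
                 kept = k_out, seed = as.integer(seed)),
    train = cells, n_train = n, call = match.call()
  ), class = "gblup_ge")
}

#' Posterior-mean predictions from a GBLUP fit
#'
#' The prediction for cell (i, j) is the posterior mean of its linear
#' predictor, E_i + g_j + gE_ij -- for training and testing cells alike
#' (a training cell's prediction is its fitted value, not the observed
#' record).
#'
#' @param object a `gblup_ge` fit.
#' @param cells `NULL` for all N cells (canonical order) or a data.frame
#'   with columns `Env` and `Line`.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.gblup_ge <- function(object, cells = NULL, ...) {
  if (is.null(cells)) return(object$yhat)
  i <- match(as.character(cells$Env), object$envs)
  j <- match(as.character(cells$Line), object$lines)
  if (anyNA(i)) stop("unknown environment: ", cells$Env[which(is.na(i))[1L]])
  if (anyNA(j)) stop("unknown line: ", cells$Line[which(is.na(j))[1L]])
  object$beta[i] + object$g[j] + object$ge[cbind(j, i)]
}

#' @export
coef.gblup_ge <- function(object, ...) {
  list(beta = object$beta, g = object$g, ge = object$ge)
}

#' @export
print.gblup_ge <- function(x, ...) {
  cat(sprintf("Bayesian GBLUP with GxE -- trait '%s'\n", x$trait))
  cat(sprintf("  %d lines, %d environments, %d training records\n",
              length(x$lines), length(x$envs), x$n_train))
  cat(sprintf("  chain: %d iterations (burn-in %d, thin %d, %d kept, seed %d)\n",
              x$chain$niter, x$chain$burnin, x$chain$thin, x$chain$kept,
              x$chain$seed))
  v <- x$variances
  cat(sprintf("  posterior-mean variances: genomic %.4g, GxE %.4g, residual %.4g\n",
              v["sigma2_g"], v["sigma2_ge"], v["sigma2_e"]))
  invisible(x)
}

#' @export
summary.gblup_ge <- function(object, ...) {
  vd <- object$draws$variances
  out <- list(
    trait = object$trait,
    variances = data.frame(
      mean = colMeans(vd), sd = apply(vd, 2L, stats::sd),
      q025 = apply(vd, 2L, stats::quantile, 0.025),
      q975 = apply(vd, 2L, stats::quantile, 0.975)),
    beta = data.frame(mean = colMeans(object$draws$beta),
                      sd = apply(object$draws$beta, 2L, stats::sd)),
    chain = object$chain)
  class(out) <- "summary.gblup_ge"
  out
}

#' @export
print.summary.gblup_ge <- function(x, ...) {
  cat(sprintf("Bayesian GBLUP with GxE -- trait '%s'\n", x$trait))
  cat("\nVariance components (posterior):\n")
  print(round(x$variances, 4))
  cat("\nEnvironment effects (posterior):\n")
  print(round(x$beta, 4))
  invisible(x)
}
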