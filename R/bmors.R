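#' Bayesian ridge regression by Gibbs sampling
#'
#' Regresses `y` on the columns of `Z` with an intercept.  Coefficients
#' share a common Gaussian prior N(0, sigma2_beta); the intercept gets a
#' vague N(0, 1e10) prior.  sigma2_beta and the residual variance carry
#' scaled inverse chi-square priors with scales Var(y) * R2 * (df + 2)
#' (R2 = 0.5 for the coefficients, 0.25 for the residual, by default).
#'
#' @param y numeric response (training records).
#' @param Z numeric n x L covariate matrix.
#' @param control an [mcmc_control()].
#' @param seed integer seed.
#' @param df_beta,df_e prior degrees of freedom (5, 5).
#' @param R2_beta,R2_e prior variance shares (0.5, 0.25).
#' @param fix_sigma2_beta,fix_sigma2_e optional values at which to freeze
#'   the corresponding variance instead of sampling it.
#' @return object of class `bayes_ridge`: posterior means `intercept`,
#'   `beta`, `sigma2_beta`, `sigma2_e`, retained draws, chain metadata.
#' @export
bayes_ridge <- function(y, Z, control = mcmc_control(), seed = 1L,
                        df_beta = 5, df_e = 5, R2_beta = 0.5, R2_e = 0.25,
                        fix_sigma2_beta = NULL, fix_sigma2_e = NULL) {
  Z <- as.matrix(Z)
  n <- length(y)
  if (n < 2L) stop("need at least 2 training records")
  if (nrow(Z) != n) stop("y and Z disagree in length")
  L <- ncol(Z)
  vary <- stats::var(y)
  if (vary <= 0) vary <- 1e-8
  S_b <- vary * R2_beta * (df_beta + 2)
  S_e <- vary * R2_e * (df_e + 2)

  D <- cbind(`(Intercept)` = 1, Z)
  DtD <- crossprod(D)
  Dty <- drop(crossprod(D, y))

  set.seed(as.integer(seed) %% .Machine$integer.max)
  s2b <- if (is.null(fix_sigma2_beta)) vary * R2_beta else fix_sigma2_beta
  s2e <- if (is.null(fix_sigma2_e)) vary * R2_e else fix_sigma2_e
  theta <- numeric(L + 1L)

  ctl <- control
  kept <- (ctl$niter - ctl$burnin) %/% ctl$thin
  coef_draws <- matrix(NA_real_, kept, L + 1L,
                       dimnames = list(NULL, colnames(D)))
  var_draws <- matrix(NA_real_, kept, 2L,
                      dimnames = list(NULL, c("sigma2_beta", "sigma2_e")))
  k_out <- 0L
  for (it in seq_len(ctl$niter)) {
    theta <- draw_gaussian_block(DtD, Dty, c(1e-10, rep(1 / s2b, L)), s2e)
    if (is.null(fix_sigma2_beta))
      s2b <- update_variance(theta[-1L], df_beta, S_b)
    if (is.null(fix_sigma2_e)) {
      rss <- sum((y - drop(D %*% theta))^2)
      s2e <- (S_e + rss) / stats::rchisq(1L, df_e + n)
    }
    if (it > ctl$burnin && (it - ctl$burnin) %% ctl$thin == 0L) {
      k_out <- k_out + 1L
      coef_draws[k_out, ] <- theta
      var_draws[k_out, ] <- c(s2b, s2e)
    }
  }
  cm <- colMeans(coef_draws)
  structure(list(
    intercept = unname(cm[1L]), beta = cm[-1L],
    sigma2_beta = mean(var_draws[, 1L]), sigma2_e = mean(var_draws[, 2L]),
    draws = list(coef = coef_draws, variances = var_draws),
    prior = list(df = c(beta = df_beta, e = df_e),
                 scale = c(beta = S_b, e = S_e), var_y = vary),
    chain = list(niter = ctl$niter, burnin = ctl$burnin, thin = ctl$thin,
                 kept = k_out, seed = as.integer(seed))
  ), class = "bayes_ridge")
}

#' @export
print.bayes_ridge <- function(x, ...) {
  cat("Bayesian ridge regression (Gibbs)\n")
  cat(sprintf("  intercept %.4g; %d coefficients\n", x$intercept,
              length(x$beta)))
  print(round(x$beta, 4))
  cat(sprintf("  sigma2_beta %.4g, sigma2_e %.4g\n", x$sigma2_beta,
              x$sigma2_e))
  invisible(x)
}

#' @export
coef.bayes_ridge <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$beta)
}

#' Column-standardize stage-one predictions
#'
#' Centers and scales each trait's prediction vector to mean 0, sample
#' standard deviation 1 (n-1 denominator), over all supplied cells.  The
#' scaled predictions are the meta-features of the second stage.
#'
#' @param raw N x L matrix of stage-one predictions.
#' @return list with `Z` (scaled N x L matrix), `center` and `scale`
#'   (per-column statistics).
#' @export
scale_predictions <- function(raw) {
  raw <- as.matrix(raw)
  ctr <- colMeans(raw)
  scl <- apply(raw, 2L, stats::sd)
  if (any(!is.finite(scl)) || any(scl <= 0))
    stop("degenerate stage-1 predictions: column ",
         colnames(raw)[which(!is.finite(scl) | scl <= 0)[1L]],
         " has zero spread")
  Z <- sweep(sweep(raw, 2L, ctr, "-"), 2L, scl, "/")
  list(Z = Z, center = ctr, scale = scl)
}

#' Bayesian multi-output regressor stacking
#'
#' Two-stage multi-trait genomic prediction.  Stage one fits, for each of
#' the L traits, the univariate [gblup_ge()] model on the training cells
#' and predicts all N cells.  The L prediction vectors are standardized
#' with [scale_predictions()] and become the covariates of stage two: for
#' each target trait, a [bayes_ridge()] meta-model of the observed
#' training records on the scaled predictions of all traits.  Final
#' predictions for any cell are intercept + sum_k beta_k * Zhat_k.
#'
#' Hidden (test) phenotypes are never touched: stage-one predictions for
#' test cells need no labels, and stage two is trained on training cells
#' only.
#'
#' @param pheno a [phenotype_grid()] with L >= 1 traits.
#' @param G genomic relationship matrix covering all lines.
#' @param train training cells (as in [gblup_ge()]); `NULL` trains on all
#'   observed cells.
#' @param control stage-one chain settings ([mcmc_control()]).
#' @param control2 stage-two chain settings; defaults to `control`.
#' @param seed integer seed used for every chain (stage-one fits are
#'   conditionally independent given the data, so a shared stream is
#'   harmless and keeps duplicate traits exactly reproducible).
#' @param inner_cv when TRUE, stage-two covariates for *training* cells
#'   are replaced by out-of-fold stage-one predictions (classic stacking);
#'   default FALSE uses in-sample fitted values.
#' @param nfolds folds for `inner_cv`.
#' @param eig optional precomputed [kernel_eigen()] of `G`.
#' @param ... further arguments passed to [gblup_ge()] (priors).
#' @return object of class `bmors`: `stage1` (list of `gblup_ge` fits),
#'   `scaling`, `Z` (N x L meta-features), `stage2` (list of
#'   `bayes_ridge` fits), `yhat` (N x L posterior-mean predictions).
#' @examples
#' sim <- simulate_scenario(J = 30, I = 2, L = 2, p = 100, seed = 3)
#' fit <- bmors(sim$pheno, sim$grm,
#'              control = mcmc_control(400, 150, 2), seed = 3)
#' fit
#' @export
bmors <- function(pheno, G, train = NULL, control = mcmc_control(),
                  control2 = control, seed = 1L, inner_cv = FALSE,
                  nfolds = 5L, eig = NULL, ...) {
  stopifnot(inherits(pheno, "pheno_grid"))
  traits <- pheno$traits
  L <- length(traits)
  N <- ncells(pheno)
  train_idx <- resolve_train(pheno, train)
  if (is.null(eig)) eig <- kernel_eigen(G[pheno$lines, pheno$lines])

  stage1 <- vector("list", L)
  names(stage1) <- traits
  P <- matrix(NA_real_, N, L, dimnames = list(NULL, traits))
  for (l in seq_len(L)) {
    stage1[[l]] <- gblup_ge(pheno, traits[l], G, train = train_idx,
                            control = control, seed = seed, eig = eig, ...)
    P[, l] <- stage1[[l]]$yhat
  }

  if (inner_cv) {
    for (l in seq_len(L)) {
      obs <- intersect(train_idx, which(!is.na(pheno$Y[, l])))
      set.seed(child_seed(seed, 7000L + l))
      fold <- sample(rep_len(seq_len(nfolds), length(obs)))
      for (f in seq_len(nfolds)) {
        hold <- obs[fold == f]
        sub <- gblup_ge(pheno, traits[l], G,
                        train = setdiff(train_idx, hold),
                        control = control, seed = seed, eig = eig, ...)
        P[hold, l] <- sub$yhat[hold]
      }
    }
  }

  scaling <- scale_predictions(P)
  Z <- scaling$Z

  stage2 <- vector("list", L)
  names(stage2) <- traits
  yhat <- matrix(NA_real_, N, L, dimnames = list(NULL, traits))
  for (l in seq_len(L)) {
    obs <- intersect(train_idx, which(!is.na(pheno$Y[, l])))
    stage2[[l]] <- bayes_ridge(pheno$Y[obs, l], Z[obs, , drop = FALSE],
                               control = control2, seed = seed)
    yhat[, l] <- stage2[[l]]$intercept + drop(Z %*% stage2[[l]]$beta)
  }

  structure(list(
    traits = traits, lines = pheno$lines, envs = pheno$envs,
    stage1 = stage1, scaling = scaling[c("center", "scale")], Z = Z,
    stage2 = stage2, yhat = yhat, train = train_idx,
    seed = as.integer(seed), inner_cv = inner_cv, call = match.call()
  ), class = "bmors")
}

#' Predictions from a BMORS fit
#'
#' @param object a `bmors` fit.
#' @param cells `NULL` for all N cells or a data.frame with `Env` and
#'   `Line` columns.
#' @param ... unused.
#' @return N (or nrow(cells)) x L matrix of predictions.
#' @export
predict.bmors <- function(object, cells = NULL, ...) {
  if (is.null(cells)) return(object$yhat)
  i <- match(as.character(cells$Env), object$envs)
  j <- match(as.character(cells$Line), object$lines)
  if (anyNA(i)) stop("unknown environment: ", cells$Env[which(is.na(i))[1L]])
  if (anyNA(j)) stop("unknown line: ", cells$Line[which(is.na(j))[1L]])
  idx <- (i - 1L) * length(object$lines) + j
  object$yhat[idx, , drop = FALSE]
}

#' @export
coef.bmors <- function(object, ...) {
  t(vapply(object$stage2, function(s) c(`(Intercept)` = s$intercept, s$beta),
           numeric(length(object$traits) + 1L)))
}

#' @export
print.bmors <- function(x, ...) {
  cat(sprintf("BMORS fit: %d traits, %d lines x %d environments\n",
              length(x$traits), length(x$lines), length(x$envs)))
  cat(sprintf("  training cells: %d of %d\n", length(x$train),
              length(x$lines) * length(x$envs)))
  cat("  stage-2 coefficients (rows = target trait):\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
summary.bmors <- function(object, ...) {
  v1 <- t(vapply(object$stage1, function(f) f$variances, numeric(3L)))
  out <- list(traits = object$traits, stage1_variances = v1,
              coefficients = coef(object),
              sigma2_beta = vapply(object$stage2, `[[`, numeric(1L),
                                   "sigma2_beta"),
              sigma2_e = vapply(object$stage2, `[[`, numeric(1L),
                                "sigma2_e"))
  class(out) <- "summary.bmors"
  out
}

#' @export
print.summary.bmors <- function(x, ...) {
  cat("BMORS summary\n\nStage-1 GBLUP posterior-mean variances:\n")
  print(round(x$stage1_variances, 4))
  cat("\nStage-2 ridge coefficients:\n")
  print(round(x$coefficients, 4))
  cat("\nStage-2 variances:\n")
  print(round(rbind(sigma2_beta = x$sigma2_beta, sigma2_e = x$sigma2_e), 4))
  invisible(x)
}

child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(k) * 9973) %% 2147483629)
}
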