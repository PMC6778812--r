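#' Random cross-validation partitions for incomplete field trials
#'
#' Each partition mimics the prediction problem of lines evaluated in
#' some, but not all, target environments.  Per partition: m =
#' round(p_testing * N) lines are drawn from the J lines -- with
#' replacement if J < m, without replacement otherwise -- and for each
#' drawn line one environment is picked uniformly at random.  The
#' resulting cells (duplicates collapsed) form the testing set; all other
#' cells are training.  Partitions are independent across repeats and
#' deterministic given the seed.
#'
#' @param pheno a [phenotype_grid()].
#' @param p_testing testing fraction in (0, 1); 0.2 and 0.4 are the usual
#'   settings.
#' @param n_partitions number of random partitions (default 10).
#' @param seed integer seed.
#' @return list of `n_partitions` partitions, each a list with integer
#'   canonical cell indices `test` and `train`.
#' @export
make_partitions <- function(pheno, p_testing = 0.2, n_partitions = 10L,
                            seed = 1L) {
  if (p_testing <= 0 || p_testing >= 1) stop("p_testing must be in (0,1)")
  J <- length(pheno$lines); I <- length(pheno$envs); N <- J * I
  m <- round(p_testing * N)
  if (m < 1L) stop("p_testing too small: empty testing set")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  lapply(seq_len(n_partitions), function(k) {
    lines <- sample.int(J, m, replace = J < m)
    envs <- sample.int(I, m, replace = TRUE)
    test <- sort(unique((envs - 1L) * J + lines))
    list(test = test, train = setdiff(seq_len(N), test))
  })
}

#' Pearson correlation between observed and predicted values
#'
#' Returns `NA` (rather than 0) when either vector has fewer than two
#' values or zero spread, so constant predictors are not silently
#' rewarded.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return correlation in \[-1, 1\], or `NA`.
#' @export
pearson_cor <- function(observed, predicted) {
  ok <- is.finite(observed) & is.finite(predicted)
  o <- observed[ok]; p <- predicted[ok]
  if (length(o) < 2L) return(NA_real_)
  if (stats::sd(o) == 0 || stats::sd(p) == 0) return(NA_real_)
  stats::cor(o, p)
}

#' Mean arctangent absolute percentage error
#'
#' Mean over records of atan(|(y - yhat) / y|), in radians, bounded in
#' \[0, pi/2\].  A record with y = 0 contributes pi/2 when the prediction
#' is nonzero (the limit of the arctangent as the relative error
#' diverges) and 0 when the prediction is also 0.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return mean error in radians.
#' @export
maape <- function(observed, predicted) {
  ok <- is.finite(observed) & is.finite(predicted)
  o <- observed[ok]; p <- predicted[ok]
  if (length(o) < 1L) return(NA_real_)
  term <- ifelse(o == 0, ifelse(p == 0, 0, pi / 2), atan(abs((o - p) / o)))
  mean(term)
}

#' Cross-validated comparison of UT-GBLUP and BMORS
#'
#' Runs the random cross-validation of [make_partitions()] and evaluates,
#' on exactly the same partitions for every model, the univariate GBLUP
#' baseline (`"UT"`) and/or the stacked model (`"BMORS"`).  When both are
#' requested, BMORS reuses the UT fits as its first stage (they are the
#' same model trained on the same cells with the same chain), which
#' halves the cost without changing either model.  Accuracy per
#' (partition, trait) is the Pearson correlation and MAAPE over the
#' observed testing cells, pooled across environments; `by_env = TRUE`
#' additionally reports per-environment metrics.
#'
#' @param pheno a [phenotype_grid()].
#' @param G genomic relationship matrix.
#' @param models character subset of `c("UT", "BMORS")`.
#' @param p_testing,n_partitions,seed see [make_partitions()].
#' @param control,control2 chain settings for stage one / stage two.
#' @param by_env also emit per-environment metric rows.
#' @param ... passed to [gblup_ge()] / [bmors()] (priors).
#' @return list of class `bmors_cv` with `metrics` (per model x trait
#'   \[x env\]: APC and MAAPE means and SDs over partitions),
#'   `per_partition` (the partition-level metrics behind the summary),
#'   `predictions` (one row per partition x model x trait x testing
#'   cell) and `partitions`.
#' @export
run_cv <- function(pheno, G, models = c("UT", "BMORS"), p_testing = 0.2,
                   n_partitions = 10L, seed = 1L,
                   control = mcmc_control(), control2 = control,
                   by_env = FALSE, ...) {
  models <- match.arg(models, c("UT", "BMORS"), several.ok = TRUE)
  parts <- make_partitions(pheno, p_testing, n_partitions, seed)
  eig <- kernel_eigen(G[pheno$lines, pheno$lines])
  traits <- pheno$traits
  J <- length(pheno$lines)
  need_bmors <- "BMORS" %in% models

  pred_rows <- list()
  met_rows <- list()
  for (k in seq_along(parts)) {
    part <- parts[[k]]
    fit_seed <- child_seed(seed, k)
    preds <- list()
    if (need_bmors) {
      fit <- bmors(pheno, G, train = part$train, control = control,
                   control2 = control2, seed = fit_seed, eig = eig, ...)
      preds[["BMORS"]] <- fit$yhat
      if ("UT" %in% models)
        preds[["UT"]] <- vapply(fit$stage1, function(f) f$yhat,
                                numeric(nrow(fit$yhat)))
    } else {
      preds[["UT"]] <- vapply(traits, function(tr)
        gblup_ge(pheno, tr, G, train = part$train, control = control,
                 seed = fit_seed, eig = eig, ...)$yhat,
        numeric(ncells(pheno)))
    }
    test <- part$test
    env_of <- (test - 1L) %/% J + 1L
    for (model in models) {
      for (l in seq_along(traits)) {
        obs <- pheno$Y[test, l]
        hat <- preds[[model]][test, l]
        seen <- !is.na(obs)
        if (sum(seen) < 2L)
          warning(sprintf(
            "partition %d, trait %s: fewer than 2 observed testing values",
            k, traits[l]))
        met_rows[[length(met_rows) + 1L]] <- data.frame(
          Partition = k, Model = model, Trait = traits[l], Env = "(all)",
          APC = pearson_cor(obs, hat), MAAPE = maape(obs, hat),
          stringsAsFactors = FALSE)
        if (by_env) {
          for (i in unique(env_of)) {
            sel <- env_of == i
            met_rows[[length(met_rows) + 1L]] <- data.frame(
              Partition = k, Model = model, Trait = traits[l],
              Env = pheno$envs[i], APC = pearson_cor(obs[sel], hat[sel]),
              MAAPE = maape(obs[sel], hat[sel]), stringsAsFactors = FALSE)
          }
        }
        pred_rows[[length(pred_rows) + 1L]] <- data.frame(
          Partition = k, Model = model, Trait = traits[l],
          Env = pheno$envs[env_of], Line = pheno$lines[(test - 1L) %% J + 1L],
          Observed = obs, Predicted = hat, stringsAsFactors = FALSE)
      }
    }
  }
  per_part <- do.call(rbind, met_rows)
  agg <- function(x) {
    x <- x[!is.na(x)]
    c(mean = if (length(x)) mean(x) else NA_real_,
      sd = if (length(x) > 1L) stats::sd(x) else NA_real_)
  }
  key <- unique(per_part[, c("Model", "Trait", "Env")])
  metrics <- do.call(rbind, lapply(seq_len(nrow(key)), function(r) {
    sel <- per_part$Model == key$Model[r] & per_part$Trait == key$Trait[r] &
      per_part$Env == key$Env[r]
    a <- agg(per_part$APC[sel]); m <- agg(per_part$MAAPE[sel])
    data.frame(Model = key$Model[r], Trait = key$Trait[r], Env = key$Env[r],
               APC = a["mean"], APC_SD = a["sd"], MAAPE = m["mean"],
               MAAPE_SD = m["sd"], row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  structure(list(metrics = metrics, per_partition = per_part,
                 predictions = do.call(rbind, pred_rows),
                 partitions = parts,
                 config = list(p_testing = p_testing,
                               n_partitions = n_partitions, seed = seed)),
            class = "bmors_cv")
}

#' @export
print.bmors_cv <- function(x, ...) {
  cat(sprintf("cross-validation: %d partitions, p_testing = %g, seed = %d\n",
              x$config$n_partitions, x$config$p_testing, x$config$seed))
  pooled <- x$metrics[x$metrics$Env == "(all)", , drop = FALSE]
  print(transform(pooled, APC = round(APC, 4), APC_SD = round(APC_SD, 4),
                  MAAPE = round(MAAPE, 4), MAAPE_SD = round(MAAPE_SD, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Write cross-validation metrics and predictions to CSV
#'
#' Emits `metrics.csv` (one row per model x trait \[x environment\] with
#' APC, APC_SD, MAAPE, MAAPE_SD) and `predictions.csv` (one row per
#' partition x model x trait x testing cell).
#'
#' @param cv a [run_cv()] result (or a compatible list with `metrics` and
#'   `predictions` data.frames).
#' @param out_dir output directory, created if needed.
#' @param dataset label for the Dataset column.
#' @return character vector of the written paths, invisibly.
#' @export
write_report <- function(cv, out_dir, dataset = "synthetic") {
  if (is.null(cv$metrics) || nrow(cv$metrics) == 0L)
    stop("empty metrics: nothing to write")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mpath <- file.path(out_dir, "metrics.csv")
  ppath <- file.path(out_dir, "predictions.csv")
  utils::write.csv(cbind(Dataset = dataset, cv$metrics), mpath,
                   row.names = FALSE)
  utils::write.csv(cv$predictions, ppath, row.names = FALSE)
  invisible(c(mpath, ppath))
}
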