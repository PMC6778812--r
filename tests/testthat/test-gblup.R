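test_that("design matrices carry one incidence per training record", {
  Y <- matrix(rnorm(6), 6, 1)
  pt <- grid_from_Y(Y, I = 2)           # 3 lines x 2 envs
  d <- build_designs(pt, "T1")
  expect_equal(dim(d$X), c(6L, 2L))
  expect_equal(dim(d$Z1), c(6L, 3L))
  expect_equal(dim(d$Z2), c(6L, 6L))
  expect_true(all(rowSums(d$X) == 1))
  expect_true(all(rowSums(d$Z1) == 1))
  expect_true(all(rowSums(d$Z2) == 1))
  expect_equal(d$y, Y[, 1])
  # masking one cell drops its row
  d5 <- build_designs(pt, "T1", train = setdiff(1:6, 4L))
  expect_equal(length(d5$y), 5L)
  expect_equal(d5$cells, c(1:3, 5:6))
  # an environment with no training records is unidentifiable
  expect_error(build_designs(pt, "T1", train = 1:3), "unidentifiable")
})

test_that("a constant response is absorbed by the environment effects", {
  J <- 15; I <- 2
  pt <- grid_from_Y(matrix(3, J * I, 1), I = I)
  G <- pd_kernel(J)
  rownames(G) <- colnames(G) <- pt$lines
  fit <- gblup_ge(pt, "T1", G, control = mcmc_control(2000, 500, 2),
                  seed = 1)
  expect_equal(unname(fit$beta), c(3, 3), tolerance = 0.02)
  expect_true(all(abs(fit$g) < 0.05 * 3))
  expect_true(all(abs(fit$ge) < 0.05 * 3))
})

test_that("chains are deterministic given data, priors, seed and settings", {
  sim <- simulate_scenario(J = 20, I = 2, L = 1, p = 60, seed = 5)
  f1 <- gblup_ge(sim$pheno, 1, sim$grm, control = mcmc_control(400, 100, 2),
                 seed = 7)
  f2 <- gblup_ge(sim$pheno, 1, sim$grm, control = mcmc_control(400, 100, 2),
                 seed = 7)
  expect_identical(f1$draws$variances, f2$draws$variances)
  expect_identical(f1$yhat, f2$yhat)
  f3 <- gblup_ge(sim$pheno, 1, sim$grm, control = mcmc_control(400, 100, 2),
                 seed = 8)
  expect_false(identical(f1$yhat, f3$yhat))
})

test_that("with identity kernel and one environment the fit is ridge", {
  set.seed(31)
  J <- 20
  y <- rnorm(J, mean = 5, sd = 1.2)
  pt <- grid_from_Y(matrix(y, J, 1), I = 1)
  G <- diag(J); dimnames(G) <- list(pt$lines, pt$lines)
  s2g <- 0.8; s2e <- 0.4
  fit <- gblup_ge(pt, "T1", G, control = mcmc_control(24000, 4000, 1),
                  seed = 2,
                  fix_variances = list(g = s2g, ge = 1e-12, e = s2e))
  # closed-form joint solve for (intercept-like env effect, g)
  D <- cbind(1, diag(J))
  C <- crossprod(D) / s2e + diag(c(1e-10, rep(1 / s2g, J)))
  mu <- drop(solve(C, crossprod(D, y) / s2e))
  expect_equal(unname(fit$beta), mu[1L], tolerance = 0.02)
  expect_equal(unname(fit$g), mu[-1L], tolerance = 0.02)
  # and that solve is the textbook ridge of centered y, penalty s2e/s2g
  lambda <- s2e / s2g
  expect_equal(mu[-1L], (y - mean(y)) / (1 + lambda), tolerance = 1e-3)
})

test_that("lines with identical kernel rows get identical predictions", {
  set.seed(41)
  J <- 8
  A <- matrix(rnorm(J * 20), J)
  A[2, ] <- A[1, ]                       # duplicate line
  G <- tcrossprod(A) / 20
  dimnames(G) <- list(paste0("L", 1:J), paste0("L", 1:J))
  y <- rnorm(2 * J); y[2] <- y[1] + 2    # data may even disagree
  pt <- grid_from_Y(matrix(y, 2 * J, 1), I = 2)
  fit <- gblup_ge(pt, "T1", G, control = mcmc_control(600, 200, 2), seed = 3)
  # prior correlation 1 forces g and gE of the twin lines to coincide
  expect_equal(fit$g[["L1"]], fit$g[["L2"]], tolerance = 1e-8)
  expect_equal(fit$ge["L1", ], fit$ge["L2", ], tolerance = 1e-8)
})

test_that("predictions are posterior means of the linear predictor", {
  sim <- simulate_scenario(J = 15, I = 2, L = 1, p = 50, seed = 6)
  fit <- gblup_ge(sim$pheno, 1, sim$grm, control = mcmc_control(800, 300, 2),
                  seed = 1)
  # training-cell prediction is the fitted value, not the observation
  expect_false(isTRUE(all.equal(fit$yhat, sim$pheno$Y[, 1])))
  expect_equal(fit$yhat[3L],
               fit$beta[[1L]] + fit$g[[3L]] + fit$ge[3L, 1L])
  # cell lookup agrees with the canonical vector
  p <- predict(fit, data.frame(Env = "E2", Line = "L4"))
  expect_equal(p, fit$yhat[15 + 4], ignore_attr = TRUE)
  expect_error(predict(fit, data.frame(Env = "E9", Line = "L1")),
               "unknown environment")
  expect_error(predict(fit, data.frame(Env = "E1", Line = "nope")),
               "unknown line")
})

test_that("collapsing the genetic variances leaves only environment means", {
  sim <- simulate_scenario(J = 12, I = 2, L = 1, p = 40, seed = 8)
  fit <- gblup_ge(sim$pheno, 1, sim$grm, control = mcmc_control(800, 300, 2),
                  seed = 2, fix_variances = list(g = 1e-12, ge = 1e-12))
  expect_true(all(abs(fit$yhat - rep(fit$beta, each = 12)) < 1e-4))
})

test_that("whole-line masking still yields kernel-informed predictions", {
  sim <- simulate_scenario(J = 40, I = 2, L = 1, p = 300, g_cor = 0,
                           seed = 9)
  # hide line L1 in every environment
  hidden <- cell_index(sim$pheno, c("E1", "E2"), c("L1", "L1"))
  fit <- gblup_ge(sim$pheno, 1, sim$grm, train = setdiff(1:80, hidden),
                  control = mcmc_control(2000, 500, 2), seed = 4)
  # the untrained line's genomic effect is drawn through G, not stuck at 0
  expect_gt(abs(fit$g[["L1"]]), 0)
  expect_true(all(is.finite(fit$yhat[hidden])))
})
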