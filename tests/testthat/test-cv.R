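test_that("line sampling switches replacement mode at m = J", {
  pt <- grid_from_Y(matrix(rnorm(15), 15, 1), I = 3)   # J=5, I=3, N=15
  # m = round(0.2*15) = 3 <= J=5: without replacement, 3 distinct cells
  parts <- make_partitions(pt, 0.2, n_partitions = 20, seed = 1)
  for (p in parts) {
    expect_equal(length(p$test), 3L)
    lines <- (p$test - 1L) %% 5L + 1L
    expect_equal(anyDuplicated(lines), 0L)
    expect_setequal(c(p$test, p$train), 1:15)
    expect_length(intersect(p$test, p$train), 0L)
  }
  # m = round(0.4*15) = 6 > J=5: with replacement, duplicates collapse
  parts4 <- make_partitions(pt, 0.4, n_partitions = 50, seed = 2)
  sizes <- lengths(lapply(parts4, `[[`, "test"))
  expect_true(all(sizes <= 6L))
  expect_true(any(sizes < 6L))   # collapsed duplicates do occur
  expect_error(make_partitions(pt, 0), "p_testing")
  expect_error(make_partitions(pt, 1.2), "p_testing")
  expect_error(make_partitions(pt, 0.01), "empty testing set")
})

test_that("partitions are deterministic given the seed", {
  pt <- grid_from_Y(matrix(rnorm(30), 30, 1), I = 3)
  a <- make_partitions(pt, 0.2, 5, seed = 11)
  b <- make_partitions(pt, 0.2, 5, seed = 11)
  expect_identical(a, b)
  c <- make_partitions(pt, 0.2, 5, seed = 12)
  expect_false(identical(a, c))
})

test_that("pearson correlation handles the textbook cases and degeneracy", {
  expect_equal(pearson_cor(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson_cor(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_cor(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_true(is.na(pearson_cor(c(1, 2, 3), c(2, 2, 2))))
  expect_true(is.na(pearson_cor(1, 1)))
  # scale- and shift-free under positive affine maps of the prediction
  o <- rnorm(20); p <- rnorm(20)
  expect_equal(pearson_cor(o, 2 * p + 7), pearson_cor(o, p))
})

test_that("MAAPE follows the arctangent conventions at zero", {
  expect_equal(maape(1, 1), 0)
  expect_equal(maape(0, 5), pi / 2)
  expect_equal(maape(0, 0), 0)
  expect_equal(maape(1, 2), pi / 4)
  # mixed vector: mean of per-record terms
  expect_equal(maape(c(1, 0), c(2, 3)), mean(c(pi / 4, pi / 2)))
  # bounded in [0, pi/2] whatever the inputs
  set.seed(1)
  for (k in 1:20) {
    v <- maape(rnorm(10), rnorm(10) * 10)
    expect_gte(v, 0); expect_lte(v, pi / 2)
  }
  # scale-sensitive, unlike Pearson
  expect_false(maape(c(1, 2), c(1.1, 2.2)) == maape(c(10, 20), c(11, 22)) + 1)
})

test_that("cross-validation applies identical partitions to every model", {
  sim <- simulate_scenario(J = 20, I = 2, L = 2, p = 60, g_cor = 0.7,
                           seed = 21)
  cv <- run_cv(sim$pheno, sim$grm, models = c("UT", "BMORS"),
               p_testing = 0.2, n_partitions = 2, seed = 5,
               control = mcmc_control(400, 150, 2))
  pr <- cv$predictions
  for (k in 1:2) {
    ut <- pr[pr$Partition == k & pr$Model == "UT" & pr$Trait == "T1", ]
    bm <- pr[pr$Partition == k & pr$Model == "BMORS" & pr$Trait == "T1", ]
    expect_identical(ut[, c("Env", "Line")], bm[, c("Env", "Line")],
                     ignore_attr = TRUE)
    expect_identical(ut$Observed, bm$Observed)
  }
  m <- cv$metrics
  expect_setequal(m$Model, c("UT", "BMORS"))
  expect_true(all(m$APC >= -1 & m$APC <= 1, na.rm = TRUE))
  expect_true(all(m$MAAPE >= 0 & m$MAAPE <= pi / 2, na.rm = TRUE))
  # summary mean/sd match a hand aggregation of the per-partition values
  sel <- cv$per_partition$Model == "UT" & cv$per_partition$Trait == "T1" &
    cv$per_partition$Env == "(all)"
  expect_equal(m$APC[m$Model == "UT" & m$Trait == "T1"],
               mean(cv$per_partition$APC[sel]))
  expect_equal(m$APC_SD[m$Model == "UT" & m$Trait == "T1"],
               sd(cv$per_partition$APC[sel]))
})

test_that("a single partition reports missing standard deviations", {
  sim <- simulate_scenario(J = 15, I = 2, L = 1, p = 40, seed = 22)
  cv <- run_cv(sim$pheno, sim$grm, models = "UT", p_testing = 0.2,
               n_partitions = 1, seed = 3,
               control = mcmc_control(300, 100, 2))
  expect_true(all(is.na(cv$metrics$APC_SD)))
  expect_true(all(is.na(cv$metrics$MAAPE_SD)))
})

test_that("per-environment metrics appear on request", {
  sim <- simulate_scenario(J = 18, I = 3, L = 1, p = 40, seed = 23)
  cv <- run_cv(sim$pheno, sim$grm, models = "UT", p_testing = 0.3,
               n_partitions = 2, seed = 4,
               control = mcmc_control(300, 100, 2), by_env = TRUE)
  expect_true(any(cv$metrics$Env != "(all)"))
  expect_true(all(c("(all)") %in% cv$metrics$Env))
})
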