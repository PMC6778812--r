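test_that("missingness filter removes markers above the threshold", {
  M <- cbind(bad = c(rep(NA_real_, 9), 1), good = rep(c(0, 2), 5))
  rownames(M) <- paste0("L", 1:10)
  out <- filter_markers(M, max_missing = 0.8, min_maf = 0)
  expect_equal(colnames(out$markers), "good")
  expect_equal(out$log$rule, "missingness")
  expect_equal(out$log$value, 0.9)
})

test_that("MAF removal is inclusive at the threshold", {
  # p_hat = mean(dosage)/2 = 0.05 -> removed under min_maf = 0.05
  M <- cbind(rare = c(rep(0, 9), 1), common = rep(c(0, 2), 5))
  rownames(M) <- paste0("L", 1:10)
  out <- filter_markers(M, min_maf = 0.05)
  expect_equal(colnames(out$markers), "common")
  expect_equal(out$log$rule, "maf")
  expect_equal(out$log$value, 0.05)
  # strictly above threshold survives
  M2 <- cbind(ok = c(rep(0, 8), 1, 1), common = rep(c(0, 2), 5))
  rownames(M2) <- paste0("L", 1:10)
  expect_equal(ncol(filter_markers(M2, min_maf = 0.05)$markers), 2L)
})

test_that("clean balanced markers pass QC untouched; empty result errors", {
  M <- matrix(rep(c(0, 2), 10), 4, 5,
              dimnames = list(paste0("L", 1:4), paste0("M", 1:5)))
  out <- filter_markers(M, max_missing = 0.8, min_maf = 0.05, max_het = 0.1)
  expect_identical(out$markers, M)
  expect_equal(nrow(out$log), 0L)
  Mono <- matrix(0, 4, 2, dimnames = list(paste0("L", 1:4), c("a", "b")))
  expect_error(filter_markers(Mono), "no markers survive")
})

test_that("heterozygosity filter drops markers with too many dosage-1 calls", {
  M <- cbind(het = c(1, 1, 1, 0, 2, 0, 2, 0, 2, 1),
             hom = rep(c(0, 2), 5))
  rownames(M) <- paste0("L", 1:10)
  out <- filter_markers(M, min_maf = 0.01, max_het = 0.10)
  expect_equal(out$log$rule, "heterozygosity")
  expect_equal(colnames(out$markers), "hom")
  # disabled by default
  expect_equal(ncol(filter_markers(M, min_maf = 0.01)$markers), 2L)
})

test_that("column-mean imputation fills gaps and leaves the rest alone", {
  M <- cbind(a = c(0, 2, NA), b = c(2, NA, NA), c = c(1, 1, 1))
  rownames(M) <- paste0("L", 1:3)
  out <- impute_markers(M)
  expect_equal(unname(out[, "a"]), c(0, 2, 1))
  expect_equal(unname(out[, "b"]), c(2, 2, 2))
  expect_equal(unname(out[, "c"]), c(1, 1, 1))
  expect_identical(impute_markers(out), out)
  M[, "c"] <- NA_real_
  expect_error(impute_markers(M), "no non-missing")
})

test_that("GRM formula G = WW'/p reproduces a hand computation", {
  # already-centered dosage columns: W = [[1,-1],[-1,1]], p = 2
  W <- matrix(c(1, -1, -1, 1), 2, 2,
              dimnames = list(c("A", "B"), c("M1", "M2")))
  G <- compute_grm(W, center = FALSE)
  expect_equal(unname(G), matrix(c(1, -1, -1, 1), 2), tolerance = 1e-14)
  # single centered marker collapses to ww'
  w <- matrix(c(1, 0, -1), 3, 1, dimnames = list(c("A", "B", "C"), "M1"))
  expect_equal(unname(compute_grm(w, center = FALSE)),
               tcrossprod(c(1, 0, -1)), tolerance = 1e-14)
})

test_that("GRM is symmetric PSD and centering removes allele-label effects", {
  M <- simulate_markers(20, 50, seed = 7)
  G <- compute_grm(M)
  expect_identical(G, t(G))
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))
  # swapping allele labels (dosage -> 2 - dosage) leaves the centered G alone
  expect_equal(compute_grm(2 - M), G, tolerance = 1e-12)
})

test_that("GRM is invariant to marker permutation and duplication", {
  M <- simulate_markers(15, 40, seed = 3)
  G <- compute_grm(M)
  expect_equal(compute_grm(M[, sample(ncol(M))]), G, tolerance = 1e-12)
  expect_equal(compute_grm(cbind(M, M)), G, tolerance = 1e-12)
})

test_that("trace identity: trace(WW'/p) equals total sum of squares over p", {
  M <- simulate_markers(12, 30, seed = 9)
  W <- sweep(M, 2, colMeans(M))
  G <- compute_grm(M)
  expect_equal(sum(diag(G)), sum(W^2) / ncol(W), tolerance = 1e-10)
})

test_that("kernel_eigen reconstructs the kernel and flags non-PSD input", {
  G <- pd_kernel(10)
  e <- kernel_eigen(G)
  expect_equal(e$vectors %*% (e$values * t(e$vectors)), G,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(crossprod(e$vectors), diag(e$rank), tolerance = 1e-10,
               ignore_attr = TRUE)
  B <- diag(c(1, 1, -1))
  expect_error(kernel_eigen(B), "positive semi-definite")
  # the marker GRM's centering null space is dropped, not inverted
  Gm <- compute_grm(simulate_markers(8, 100, seed = 1))
  expect_lt(kernel_eigen(Gm)$rank, 8L)
})
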