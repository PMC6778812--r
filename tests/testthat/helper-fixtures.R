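# Small fixtures built in code; no files shipped.

# tiny long-format phenotype CSV: 2 lines x 2 envs, 1 trait
write_tiny_pheno <- function(path, drop_row = NULL, duplicate = FALSE) {
  df <- data.frame(Line = c("A", "B", "A", "B"),
                   Env = c("E1", "E1", "E2", "E2"),
                   GY = c(1.5, 2.5, 3.5, 4.5))
  if (!is.null(drop_row)) df <- df[-drop_row, ]
  if (duplicate) df <- rbind(df, df[1L, ])
  write.csv(df, path, row.names = FALSE)
  path
}

# a full-rank PD kernel with line ids (not marker-derived, so no null space)
pd_kernel <- function(J, seed = 42) {
  set.seed(seed)
  A <- matrix(rnorm(J * (J + 5)), J)
  G <- tcrossprod(A) / (J + 5) + diag(0.5, J)
  dimnames(G) <- list(paste0("L", seq_len(J)), paste0("L", seq_len(J)))
  G
}

# grid with given Y matrix (canonical order), default 1 trait
grid_from_Y <- function(Y, I, traits = paste0("T", seq_len(ncol(Y)))) {
  J <- nrow(Y) / I
  structure(list(lines = paste0("L", seq_len(J)),
                 envs = paste0("E", seq_len(I)),
                 traits = traits,
                 Y = `colnames<-`(as.matrix(Y), traits)),
            class = "pheno_grid")
}

# dense prior precision for the full GxE coefficient vector (beta, g, gE)
mme_prior_precision <- function(G, I, s2g, s2ge, prec_beta = 1e-10) {
  J <- nrow(G)
  Ginv <- solve(G)
  blocks <- list(diag(prec_beta, I), Ginv / s2g,
                 kronecker(diag(I), Ginv) / s2ge)
  n <- I + J + I * J
  P <- matrix(0, n, n)
  at <- 1L
  for (b in blocks) {
    k <- nrow(b)
    P[at:(at + k - 1L), at:(at + k - 1L)] <- b
    at <- at + k
  }
  P
}
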