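# Shared fixture builders: everything is generated in code at test time.

make_random_study <- function(n_genes = 30L, n_per_batch = c(8L, 12L),
                              seed = 1L, with_covariate = TRUE,
                              gamma = NULL, delta2 = NULL, sigma = NULL,
                              beta = NULL) {
  set.seed(seed)
  k <- length(n_per_batch)
  N <- sum(n_per_batch)
  batch <- factor(rep(sprintf("B%d", seq_len(k)), n_per_batch))
  alpha <- rnorm(n_genes, 5, 1)
  sigma <- sigma %||% runif(n_genes, 0.5, 1.5)
  covariate <- if (with_covariate) rnorm(N) else NULL
  beta <- beta %||% if (with_covariate) rnorm(n_genes, 0, 0.5) else NULL
  gamma <- gamma %||% matrix(rnorm(k * n_genes, 0, 0.5), k, n_genes)
  delta2 <- delta2 %||% matrix(exp(rnorm(k * n_genes, 0, 0.3)), k, n_genes)
  Y <- matrix(0, n_genes, N)
  for (g in seq_len(n_genes)) {
    for (j in seq_len(N)) {
      i <- as.integer(batch[j])
      mu <- alpha[g] + (if (with_covariate) covariate[j] * beta[g] else 0) +
        gamma[i, g] * sigma[g]
      Y[g, j] <- mu + sqrt(delta2[i, g]) * sigma[g] * rnorm(1)
    }
  }
  rownames(Y) <- sprintf("g%03d", seq_len(n_genes))
  colnames(Y) <- sprintf("s%03d", seq_len(N))
  design <- study_design(
    batch = batch,
    covariates = if (with_covariate)
      matrix(covariate, ncol = 1, dimnames = list(NULL, "x")) else NULL)
  list(Y = Y, design = design, alpha = alpha, beta = beta, sigma = sigma,
       gamma = gamma, delta2 = delta2, batch = batch, covariate = covariate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_batchfx_error <- function(expr, class) {
  expect_error(expr, class = class)
}
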