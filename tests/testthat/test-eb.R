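# The EB machinery is checked three ways: hand-computed small cases,
# independent brute-force oracles written inline, and sva::ComBat as an
# external cross-check on the composed pipeline.

fake_fit <- function(Z, batch, reference_batch = NULL) {
  structure(list(Z = Z, batch = as.factor(batch),
                 reference_batch = reference_batch,
                 sigma = rep(1, nrow(Z)),
                 stand_mean = matrix(0, nrow(Z), ncol(Z))),
            class = "standardized_fit")
}

test_that("raw batch-effect estimates: means and unbiased variances", {
  Z <- rbind(g1 = c(-1, 1, 1, 1, 1), g2 = c(0, 2, -1, 0, 1))
  fit <- fake_fit(Z, c("A", "A", "B", "B", "B"))
  # g1 is constant within batch B: its delta^2 is flagged and floored
  expect_warning(est <- estimate_batch_effects(fit),
                 class = "zero_within_batch_variance")
  expect_equal(unname(est$gamma_hat["A", "g1"]), 0)
  expect_equal(unname(est$delta2_hat["A", "g1"]), 2)  # (1+1)/(2-1)
  expect_equal(unname(est$gamma_hat["B", "g1"]), 1)
  expect_gt(est$delta2_hat["B", "g1"], 0)

  expect_batchfx_error(
    estimate_batch_effects(fake_fit(Z, c("A", "B", "B", "B", "B"))),
    "singleton_batch_error")
})

test_that("raw estimates match a double-loop oracle on a random batch", {
  set.seed(42)
  Z <- matrix(rnorm(50 * 9), 50, 9,
              dimnames = list(sprintf("g%d", 1:50), sprintf("s%d", 1:9)))
  batch <- rep(c("A", "B", "C"), each = 3)
  est <- estimate_batch_effects(fake_fit(Z, batch))
  for (b in unique(batch)) {
    for (g in 1:50) {
      vals <- c()
      for (j in which(batch == b)) vals <- c(vals, Z[g, j])
      expect_equal(unname(est$gamma_hat[b, g]), sum(vals) / length(vals))
      expect_equal(unname(est$delta2_hat[b, g]),
                   sum((vals - mean(vals))^2) / (length(vals) - 1))
    }
  }
})

test_that("method-of-moments hyperpriors reproduce closed-form cases", {
  # V = 1, S2 = 1 -> inverse-gamma(3, 2): mean theta/(lambda-1) = 1,
  # variance theta^2/((lambda-1)^2 (lambda-2)) = 1
  gamma_hat <- matrix(c(-1, 0, 1), 1, 3)
  delta2_hat <- matrix(c(1 - sqrt(1.5), 1, 1 + sqrt(1.5)), 1, 3)
  expect_equal(mean(delta2_hat), 1)
  expect_equal(var(as.numeric(delta2_hat)), 1.5)
  h <- fit_hyperpriors(gamma_hat, delta2_hat)
  V <- 1; S2 <- 1.5
  expect_equal(h$lambda, (2 * S2 + V^2) / S2)
  expect_equal(h$theta, (V * S2 + V^3) / S2)
  expect_equal(h$theta / (h$lambda - 1), V)
  expect_equal(h$theta^2 / ((h$lambda - 1)^2 * (h$lambda - 2)), S2)
  expect_equal(h$gamma_bar, 0)
  expect_equal(h$tau2_bar, 1)

  expect_batchfx_error(
    fit_hyperpriors(gamma_hat, matrix(2, 1, 3)), "degenerate_prior_error")
})

test_that("mean-only posteriors are the closed-form convex combination", {
  Z <- rbind(g1 = c(0, 0, 4, 4), g2 = c(1, -1, 0, 2), g3 = c(2, 0, 1, 1))
  fit <- fake_fit(Z, c("A", "A", "B", "B"))
  est <- estimate_batch_effects(fit, variance = FALSE)
  h <- fit_hyperpriors(est$gamma_hat, est$delta2_hat, variance = FALSE)
  post <- solve_posteriors(est$gamma_hat, est$delta2_hat, h, fit,
                           mode = "mean_only")
  expect_true(all(post$delta2_star == 1))
  n <- 2
  for (i in 1:2) {
    nt2 <- n * h$tau2_bar[i]
    expect_equal(post$gamma_star[i, ],
                 (nt2 * est$gamma_hat[i, ] + h$gamma_bar[i]) / (nt2 + 1))
  }
  # with n tau2 = 1 the posterior is the midpoint of gamma_hat and gamma_bar
  h2 <- h; h2$tau2_bar <- c(0.5, 0.5)
  post2 <- solve_posteriors(est$gamma_hat, est$delta2_hat, h2, fit,
                            mode = "mean_only")
  expect_equal(post2$gamma_star,
               (est$gamma_hat + rowMeans(est$gamma_hat)) / 2)
})

test_that("a diffuse gamma prior leaves the raw estimates unshrunk", {
  st <- make_random_study(n_genes = 25L, n_per_batch = c(6L, 6L), seed = 9)
  fit <- fit_location_scale(st$Y, st$design)
  est <- estimate_batch_effects(fit)
  h <- fit_hyperpriors(est$gamma_hat, est$delta2_hat)
  h$tau2_bar <- c(1e12, 1e12)
  post <- solve_posteriors(est$gamma_hat, est$delta2_hat, h, fit, "original")
  expect_equal(post$gamma_star, est$gamma_hat, tolerance = 1e-5)
})

test_that("posterior fixed point matches a 10,000-iteration brute force", {
  set.seed(3)
  Z <- matrix(rnorm(3 * 4, mean = 0.5), 3, 4,
              dimnames = list(c("g1", "g2", "g3"), NULL))
  fit <- fake_fit(Z, rep("A", 4))
  # single batch is fine at this layer; posteriors are per (batch, gene)
  est <- estimate_batch_effects(fit)
  h <- fit_hyperpriors(est$gamma_hat, est$delta2_hat)
  post <- solve_posteriors(est$gamma_hat, est$delta2_hat, h, fit, "original",
                           conv = 1e-12, max_iter = 100000L)
  # independent scalar-loop oracle
  n <- 4
  for (g in 1:3) {
    gh <- unname(est$gamma_hat[1, g]); g_cur <- gh
    d_cur <- unname(est$delta2_hat[1, g])
    for (iter in 1:10000) {
      g_cur <- (n * h$tau2_bar * gh + d_cur * h$gamma_bar) /
        (n * h$tau2_bar + d_cur)
      s2 <- 0
      for (j in 1:n) s2 <- s2 + (Z[g, j] - g_cur)^2
      d_cur <- unname((h$theta + 0.5 * s2) / (n / 2 + h$lambda - 1))
    }
    expect_equal(unname(post$gamma_star[1, g]), g_cur, tolerance = 1e-8)
    expect_equal(unname(post$delta2_star[1, g]), d_cur, tolerance = 1e-8)
  }
})

test_that("non-convergence raises a classed error", {
  st <- make_random_study(n_genes = 10L, n_per_batch = c(5L, 5L), seed = 2)
  fit <- fit_location_scale(st$Y, st$design)
  est <- estimate_batch_effects(fit)
  h <- fit_hyperpriors(est$gamma_hat, est$delta2_hat)
  expect_batchfx_error(
    solve_posteriors(est$gamma_hat, est$delta2_hat, h, fit, "original",
                     conv = 1e-15, max_iter = 2L),
    "non_convergence_error")
})

test_that("shrinkage pulls every posterior between estimate and prior mean", {
  st <- make_random_study(n_genes = 40L, n_per_batch = c(8L, 10L), seed = 7)
  res <- combat(st$Y, st$design, mode = "original")
  m <- res$model
  for (i in 1:2) {
    lo <- pmin(m$gamma_hat[i, ], m$hyper$gamma_bar[i]) - 1e-8
    hi <- pmax(m$gamma_hat[i, ], m$hyper$gamma_bar[i]) + 1e-8
    expect_true(all(m$gamma_star[i, ] >= lo & m$gamma_star[i, ] <= hi))
  }
  resm <- combat(st$Y, st$design, mode = "mean_only")
  mm <- resm$model
  for (i in 1:2) {
    lo <- pmin(mm$gamma_hat[i, ], mm$hyper$gamma_bar[i]) - 1e-12
    hi <- pmax(mm$gamma_hat[i, ], mm$hyper$gamma_bar[i]) + 1e-12
    expect_true(all(mm$gamma_star[i, ] >= lo & mm$gamma_star[i, ] <= hi))
  }
})

test_that("mean-only adjustment preserves within-batch variances exactly", {
  st <- make_random_study(n_genes = 50L, n_per_batch = c(10L, 15L), seed = 8)
  out <- combat(st$Y, st$design, mode = "mean_only")$adjusted
  for (l in levels(st$batch)) {
    idx <- st$batch == l
    expect_equal(apply(out[, idx], 1, var), apply(st$Y[, idx], 1, var),
                 tolerance = 1e-10)
  }
})

test_that("reference batch is returned bit-identical", {
  st <- make_random_study(n_genes = 30L, n_per_batch = c(8L, 8L), seed = 10)
  st$design$reference_batch <- "B2"
  out <- combat(st$Y, st$design, mode = "reference")
  idx <- st$batch == "B2"
  expect_identical(out$adjusted[, idx], st$Y[, idx])
  expect_equal(unname(out$model$gamma_star[2, ]), rep(0, 30))
  expect_equal(unname(out$model$delta2_star[2, ]), rep(1, 30))
})

test_that("adjusting two identically distributed batches is near a no-op", {
  set.seed(21)
  n <- 500L
  Y <- matrix(rnorm(40 * 2 * n, mean = 3, sd = 1), 40, 2 * n)
  rownames(Y) <- sprintf("g%d", 1:40)
  d <- study_design(rep(c("A", "B"), each = n))
  out <- combat(Y, d, mode = "original")$adjusted
  shift <- abs(rowMeans(out) - rowMeans(Y))
  se <- 1 / sqrt(2 * n)
  expect_lt(max(shift), 3 * se)
})

test_that("repeated original-mode adjustment is a contraction", {
  # exact idempotence is not a property of the EB procedure: after one pass
  # the raw second-pass effects are shrinkage residues, not exactly (0, 1),
  # so each further pass moves the data by ever smaller amounts
  st <- make_random_study(n_genes = 60L, n_per_batch = c(12L, 12L), seed = 12)
  once <- combat(st$Y, st$design, mode = "original")$adjusted
  twice <- combat(once, st$design, mode = "original")$adjusted
  thrice <- combat(twice, st$design, mode = "original")$adjusted
  d1 <- max(abs(once - st$Y))
  d2 <- max(abs(twice - once))
  d3 <- max(abs(thrice - twice))
  expect_lt(d2, d1)
  expect_lt(d3, d2)
  # the second pass finds much less additive batch effect to remove
  refit <- combat(once, st$design, mode = "original")$model
  expect_lt(max(abs(refit$gamma_hat)), 0.5 * max(abs(
    combat(st$Y, st$design, mode = "original")$model$gamma_hat)))
})

test_that("adjustment commutes with sample permutation", {
  st <- make_random_study(n_genes = 20L, n_per_batch = c(6L, 8L), seed = 13)
  out <- combat(st$Y, st$design, mode = "original")$adjusted
  set.seed(2)
  perm <- sample(ncol(st$Y))
  d2 <- study_design(st$batch[perm],
                     covariates = st$design$covariates[perm, , drop = FALSE])
  out2 <- combat(st$Y[, perm], d2, mode = "original")$adjusted
  expect_equal(out2, out[, perm])
})

test_that("single-batch input cannot be adjusted", {
  st <- make_random_study(n_genes = 10L, n_per_batch = 8L, seed = 14)
  expect_batchfx_error(combat(st$Y, st$design, "original"),
                       "single_batch_error")
})

test_that("original and reference modes agree with sva::ComBat", {
  suppressMessages(library(sva))
  st <- make_random_study(n_genes = 80L, n_per_batch = c(10L, 14L), seed = 20)
  mod <- stats::model.matrix(~st$covariate)

  mine <- combat(st$Y, st$design, mode = "original")$adjusted
  theirs <- suppressMessages(
    sva::ComBat(st$Y, batch = st$batch, mod = mod))
  expect_equal(unname(mine), unname(theirs), tolerance = 1e-3)

  st$design$reference_batch <- "B1"
  mine_ref <- combat(st$Y, st$design, mode = "reference")$adjusted
  theirs_ref <- suppressMessages(
    sva::ComBat(st$Y, batch = st$batch, mod = mod, ref.batch = "B1"))
  expect_equal(unname(mine_ref), unname(theirs_ref), tolerance = 1e-3)
})

test_that("degenerate delta priors fall back to unshrunken variances", {
  # two genes with identical within-batch spread make S2 = 0
  Y <- rbind(g1 = c(0, 1, 2, 10, 11, 12), g2 = c(5, 6, 7, -1, 0, 1))
  d <- study_design(rep(c("A", "B"), each = 3))
  expect_warning(res <- combat(Y, d, mode = "original"),
                 class = "degenerate_prior_fallback")
  expect_equal(res$model$delta2_star, res$model$delta2_hat)
})
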