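# Synthetic-data generators and evaluation harnesses. All generators are
# pure functions of their seed and parameters; the caller's RNG state is
# saved and restored.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Simulate the two-batch pathway-signature study
#'
#' Batch 1 emulates a small, tightly controlled perturbation experiment: 200
#' genes x 6 samples, three replicates before and three after pathway
#' activation. The first 100 genes are signature genes (mean 0 before, 1
#' after); the remaining 100 are controls (mean 0 throughout); noise scale
#' 0.1. Batch 2 emulates a large, highly variable patient cohort: the same
#' 200 genes x 600 samples in six equal subgroups with graded pathway
#' activation; signature genes have mean mu in {0.5, 0.7, ..., 1.5} by
#' subgroup, controls mean 0.5, noise scale 10.
#'
#' @param seed Integer seed; regeneration with the same seed is
#'   bit-identical.
#' @param scale_param_is_variance Interpret the noise scale parameters (0.1
#'   and 10) as variances (`TRUE`) or standard deviations (`FALSE`, the
#'   default). The default is the standard-deviation reading: it produces
#'   the regime this study is designed to exhibit, where the patient batch's
#'   noise swamps the signature when the batches are naively combined (see
#'   the methods vignette).
#' @return Object of class `simulated_study`: `expression` (200 x 606
#'   matrix, batch 1 columns first), `design` (a [study_design()] with the
#'   activation level as covariate), `gene_truth` (factor,
#'   signature/control), `sample_groups`, `pathway_activation`, `seed`.
#' @export
simulate_pathway_study <- function(seed, scale_param_is_variance = FALSE) {
  sd1 <- if (scale_param_is_variance) sqrt(0.1) else 0.1
  sd2 <- if (scale_param_is_variance) sqrt(10) else 10
  n_genes <- 200L
  sig <- seq_len(100L)
  mu_groups <- c(0.5, 0.7, 0.9, 1.1, 1.3, 1.5)

  with_seed(seed, {
    mean1 <- matrix(0, n_genes, 6)
    mean1[sig, 4:6] <- 1
    b1 <- mean1 + sd1 * matrix(stats::rnorm(n_genes * 6), n_genes, 6)

    mu_j <- rep(mu_groups, each = 100)
    mean2 <- matrix(0.5, n_genes, 600)
    mean2[sig, ] <- rep(mu_j, each = length(sig))
    b2 <- mean2 + sd2 * matrix(stats::rnorm(n_genes * 600), n_genes, 600)

    Y <- cbind(b1, b2)
    rownames(Y) <- sprintf("gene_%03d", seq_len(n_genes))
    colnames(Y) <- c(sprintf("b1_s%d", 1:6), sprintf("b2_s%03d", 1:600))
    activation <- c(rep(c(0, 1), each = 3), mu_j)
    design <- study_design(
      batch = rep(c("batch1", "batch2"), c(6, 600)),
      covariates = matrix(activation, ncol = 1,
                          dimnames = list(NULL, "activation")))
    structure(list(
      expression = Y,
      design = design,
      gene_truth = factor(rep(c("signature", "control"), each = 100),
                          levels = c("signature", "control")),
      sample_groups = c(rep(c("before", "after"), each = 3),
                        sprintf("group%d", rep(1:6, each = 100))),
      pathway_activation = activation,
      seed = seed), class = "simulated_study")
  })
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("simulated_study: %d genes x %d samples, batches: %s (seed %d)\n",
              nrow(x$expression), ncol(x$expression),
              paste(sprintf("%s n=%d", levels(x$design$batch),
                            tabulate(x$design$batch)), collapse = ", "),
              x$seed))
  invisible(x)
}

#' Signature-recovery accuracy of k-means gene clustering
#'
#' Each gene is one observation vector (dimension = number of samples in the
#' supplied matrix). Genes are split into `k = 2` groups by k-means with
#' Euclidean distance, keeping the best of `n_restarts` initializations, and
#' accuracy is the maximum fraction of correctly labeled genes over the two
#' ways of assigning clusters to the signature/control labels. For balanced
#' truth the metric therefore lies in [0.5, 1].
#'
#' @param expression Gene-by-sample matrix.
#' @param gene_truth Factor or logical; the first level (or `TRUE`) marks
#'   signature genes.
#' @param k Number of clusters (2).
#' @param n_restarts Independent k-means initializations (default 25).
#' @param seed Optional seed for the k-means initializations.
#' @return Accuracy fraction in [0, 1].
#' @export
kmeans_signature_accuracy <- function(expression, gene_truth, k = 2L,
                                      n_restarts = 25L, seed = NULL) {
  if (nrow(expression) < k) {
    bfx_error("fewer genes than clusters", "dimension_error")
  }
  is_sig <- if (is.logical(gene_truth)) gene_truth
            else gene_truth == (levels(as.factor(gene_truth))[1L])
  run <- function() stats::kmeans(expression, centers = k,
                                  nstart = n_restarts, iter.max = 300L)
  km <- if (is.null(seed)) run() else with_seed(seed, run())
  max(mean((km$cluster == 1L) == is_sig),
      mean((km$cluster == 2L) == is_sig))
}

#' Pathway benchmark: signature recovery before and after adjustment
#'
#' Generates the two-batch pathway study, adjusts the combined matrix with
#' original-mode and reference-mode (reference = batch 1) empirical Bayes
#' adjustment, and scores k-means signature recovery on batch 1 alone, batch
#' 2 alone, and the combined data for each of unadjusted / original /
#' reference.
#'
#' @param seed Seed for the generator (k-means restarts are derived from it).
#' @param use_covariates Include the true pathway activation level as a
#'   covariate in the adjustment (the benchmark's main configuration).
#' @param scale_param_is_variance Passed to [simulate_pathway_study()].
#' @param n_restarts k-means restarts per cell.
#' @return Data frame with columns `adjustment` (none/original/reference),
#'   `subset` (batch1/batch2/combined) and `accuracy`.
#' @export
run_pathway_benchmark <- function(seed, use_covariates = TRUE,
                                  scale_param_is_variance = FALSE,
                                  n_restarts = 25L) {
  study <- simulate_pathway_study(seed, scale_param_is_variance)
  design <- study$design
  if (!use_covariates) design$covariates <- NULL
  design$reference_batch <- "batch1"

  Y <- study$expression
  adj_orig <- combat(Y, design, mode = "original")$adjusted
  adj_ref <- combat(Y, design, mode = "reference")$adjusted

  idx1 <- design$batch == "batch1"
  mats <- list(none = Y, original = adj_orig, reference = adj_ref)
  subsets <- list(batch1 = idx1, batch2 = !idx1,
                  combined = rep(TRUE, ncol(Y)))
  out <- expand.grid(adjustment = names(mats), subset = names(subsets),
                     stringsAsFactors = FALSE)
  out$accuracy <- mapply(function(a, s) {
    kmeans_signature_accuracy(mats[[a]][, subsets[[s]], drop = FALSE],
                              study$gene_truth, n_restarts = n_restarts,
                              seed = seed + 7L)
  }, out$adjustment, out$subset)
  out
}

#' Simulate a two-batch differential-expression study
#'
#' Two batches, each containing both condition groups (balanced). Baseline
#' expression is N(0, 1); the first `n_de` genes gain `effect_size` in
#' condition 2. Batch 2 carries an additive shift of `gamma_shift` in the
#' mean regimes and a residual-variance inflation of `delta2_factor` in the
#' mean-and-variance regime.
#'
#' @param seed Integer seed.
#' @param batch_effect `"none"`, `"mean_only"` or `"mean_and_variance"`.
#' @param n_genes,n_de Total and differentially expressed gene counts.
#' @param n_per_group Samples per (batch, condition) cell.
#' @param effect_size Condition-2 shift for DE genes.
#' @param gamma_shift Additive batch-2 effect (mean regimes).
#' @param delta2_factor Multiplicative batch-2 residual-variance factor
#'   (variance regime).
#' @return A `simulated_study`; `sample_groups` holds the condition labels
#'   and `gene_truth` marks DE genes as "signature".
#' @export
simulate_de_study <- function(seed,
                              batch_effect = c("none", "mean_only",
                                               "mean_and_variance"),
                              n_genes = 1000L, n_de = 100L,
                              n_per_group = 10L, effect_size = 1,
                              gamma_shift = 1, delta2_factor = 4) {
  batch_effect <- match.arg(batch_effect)
  if (n_de > n_genes) bfx_error("n_de exceeds n_genes", "dimension_error")
  if (n_per_group < 2L) bfx_error("need n_per_group >= 2", "dimension_error")
  N <- 4L * n_per_group
  batch <- rep(c("batch1", "batch2"), each = 2L * n_per_group)
  condition <- rep(rep(c("ctrl", "case"), each = n_per_group), 2L)

  with_seed(seed, {
    m <- matrix(0, n_genes, N)
    if (n_de > 0) m[seq_len(n_de), condition == "case"] <- effect_size
    if (batch_effect != "none") m[, batch == "batch2"] <-
      m[, batch == "batch2"] + gamma_shift
    noise_sd <- matrix(1, n_genes, N)
    if (batch_effect == "mean_and_variance") {
      noise_sd[, batch == "batch2"] <- sqrt(delta2_factor)
    }
    Y <- m + noise_sd * matrix(stats::rnorm(n_genes * N), n_genes, N)
    rownames(Y) <- sprintf("gene_%04d", seq_len(n_genes))
    colnames(Y) <- sprintf("%s_%s_%d", batch, condition,
                           rep(seq_len(n_per_group), 4L))
    design <- study_design(
      batch = batch,
      covariates = matrix(as.numeric(condition == "case"), ncol = 1,
                          dimnames = list(NULL, "condition")))
    structure(list(
      expression = Y,
      design = design,
      gene_truth = factor(rep(c("signature", "control"),
                              c(n_de, n_genes - n_de)),
                          levels = c("signature", "control")),
      sample_groups = condition,
      pathway_activation = as.numeric(condition == "case"),
      seed = seed), class = "simulated_study")
  })
}

#' Row-wise pooled-variance two-sample t test
#'
#' The DE evaluation harness's internal test: equal-variance two-sample t
#' per gene (row) with p from the t distribution on n1 + n2 - 2 degrees of
#' freedom.
#'
#' @param Y Gene-by-sample matrix.
#' @param group Logical or two-level factor splitting the columns.
#' @return Data frame with `statistic` and `p_value`, one row per gene.
#' @export
row_t_test <- function(Y, group) {
  g <- if (is.logical(group)) group else group == levels(as.factor(group))[1L]
  n1 <- sum(g); n2 <- sum(!g)
  stopifnot(n1 >= 2, n2 >= 2)
  Y1 <- Y[, g, drop = FALSE]; Y2 <- Y[, !g, drop = FALSE]
  m1 <- rowMeans(Y1); m2 <- rowMeans(Y2)
  ss1 <- rowSums((Y1 - m1)^2); ss2 <- rowSums((Y2 - m2)^2)
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  data.frame(statistic = tstat,
             p_value = 2 * stats::pt(-abs(tstat), n1 + n2 - 2))
}

#' Type-I error and power of DE detection under batch adjustment
#'
#' Per replicate: simulate a two-batch DE study, optionally batch-adjust it,
#' test each gene for a condition difference with the internal pooled t test,
#' and reject at `alpha`. Type-I error is the rejection fraction among
#' non-DE genes, power the fraction among DE genes; both are averaged over
#' replicates.
#'
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param batch_effect Regime passed to [simulate_de_study()].
#' @param combat_mode `"none"` (no adjustment), `"original"` or
#'   `"mean_only"`.
#' @param n_reps Number of replicates.
#' @param alpha Test level.
#' @param ... Further arguments to [simulate_de_study()].
#' @return List with `type1_error`, `power`, `n_reps`, and the per-replicate
#'   rates.
#' @export
evaluate_type1_power <- function(seed, batch_effect, combat_mode = "none",
                                 n_reps = 50L, alpha = 0.05, ...) {
  per_rep <- vapply(seq_len(n_reps), function(r) {
    study <- simulate_de_study(seed + r, batch_effect = batch_effect, ...)
    Y <- study$expression
    if (combat_mode != "none") {
      Y <- combat(Y, study$design, mode = combat_mode)$adjusted
    }
    res <- row_t_test(Y, study$sample_groups == "case")
    de <- study$gene_truth == "signature"
    rej <- res$p_value < alpha
    c(type1 = mean(rej[!de]), power = mean(rej[de]))
  }, numeric(2))
  list(type1_error = mean(per_rep["type1", ]),
       power = mean(per_rep["power", ]),
       n_reps = n_reps,
       per_replicate = t(per_rep))
}
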