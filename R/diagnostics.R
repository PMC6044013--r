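#' Moment estimates of standardized expression, per sample or per gene
#'
#' On the standardized scale Z the batch effects appear as differences in the
#' distributional moments across batches. The sample-level table estimates,
#' within each sample j, the mean \eqn{\bar\gamma_{ij} = n_g^{-1} \sum_g
#' Z_{ijg}} plus the variance, skewness and kurtosis of the Z values over
#' genes. The gene-level table estimates, within each (gene, batch) cell, the
#' mean \eqn{\bar\gamma_{ig} = n_i^{-1} \sum_j Z_{ijg}} plus variance,
#' skewness and kurtosis over the batch's samples.
#'
#' Variance is the unbiased estimator; skewness and kurtosis are the
#' central-moment g1 and g2 forms (excess kurtosis, normal -> 0), computed by
#' `e1071` with `type = 1`. Moments needing more observations than a unit has
#' (variance 2, skewness 3, kurtosis 4) are reported NA.
#'
#' @param fit A [fit_location_scale()] result (or [batch_diagnostics()] will
#'   build one for you from raw data).
#' @param level `"sample"` (one unit per sample) or `"gene"` (one unit per
#'   gene-batch pair).
#' @return Object of class `moment_table`: list with `level`, `estimates`
#'   (units x 4 matrix: mean, variance, skewness, kurtosis) and `batch`
#'   (batch label per unit).
#' @export
compute_moments <- function(fit, level = c("sample", "gene")) {
  level <- match.arg(level)
  Z <- fit$Z
  batch <- fit$batch

  unit_moments <- function(x) {
    n <- length(x)
    c(mean = mean(x),
      variance = if (n >= 2) stats::var(x) else NA_real_,
      skewness = if (n >= 3) e1071::skewness(x, type = 1) else NA_real_,
      kurtosis = if (n >= 4) e1071::kurtosis(x, type = 1) else NA_real_)
  }

  if (level == "sample") {
    est <- t(apply(Z, 2, unit_moments))
    rownames(est) <- colnames(Z)
    unit_batch <- batch
  } else {
    lev <- levels(batch)
    est <- do.call(rbind, lapply(lev, function(l) {
      t(apply(Z[, batch == l, drop = FALSE], 1, unit_moments))
    }))
    rownames(est) <- paste(rep(lev, each = nrow(Z)), rownames(Z), sep = ":")
    unit_batch <- factor(rep(lev, each = nrow(Z)), levels = lev)
  }
  structure(list(level = level, estimates = est, batch = unit_batch),
            class = "moment_table")
}

# Shared sums-of-squares bookkeeping for the two F tests.
anova_pieces <- function(est, batch) {
  keep <- !is.na(est)
  est <- est[keep]
  batch <- droplevels(batch[keep])
  if (nlevels(batch) < 2L || length(est) < nlevels(batch) + 1L) {
    bfx_error("need >= 2 batches and more estimates than batches",
              "insufficient_observations_error")
  }
  list(est = est, batch = batch, M = length(est), k = nlevels(batch))
}

#' One-way F test of a moment across batches
#'
#' Standard one-way analysis of variance comparing the moment estimates of a
#' [compute_moments()] table grouped by batch, with F on (k-1, M-k) degrees
#' of freedom. When the estimates carry no variation at all (e.g. the sample
#' moments of quantile-normalized data) the test is degenerate and p = 1 by
#' convention.
#'
#' @param table A `moment_table`.
#' @param moment One of `"mean"`, `"variance"`, `"skewness"`, `"kurtosis"`.
#' @return List: `statistic`, `p_value`, `df`, `M`, `k`, `degenerate`.
#' @export
moment_anova <- function(table, moment = c("mean", "variance", "skewness",
                                           "kurtosis")) {
  moment <- match.arg(moment)
  p <- anova_pieces(table$estimates[, moment], table$batch)
  tot <- sum((p$est - mean(p$est))^2)
  if (tot < .Machine$double.eps * max(1, mean(p$est)^2) * p$M) {
    return(list(statistic = 0, p_value = 1, df = c(p$k - 1L, p$M - p$k),
                M = p$M, k = p$k, degenerate = TRUE))
  }
  gm <- tapply(p$est, p$batch, mean)
  nk <- tabulate(p$batch)
  ssb <- sum(nk * (gm - mean(p$est))^2)
  if (tot - ssb < .Machine$double.eps * tot) {
    # all within-batch spread is zero but batch means differ
    return(list(statistic = Inf, p_value = 0, df = c(p$k - 1L, p$M - p$k),
                M = p$M, k = p$k, degenerate = TRUE))
  }
  ft <- stats::oneway.test(p$est ~ p$batch, var.equal = TRUE)
  list(statistic = unname(ft$statistic), p_value = unname(ft$p.value),
       df = unname(ft$parameter), M = p$M, k = p$k, degenerate = FALSE)
}

#' Robust (variance-inflated) F test of a moment across batches
#'
#' With very many moment estimates (gene-level tests contribute one estimate
#' per gene per batch) the standard F test's p-value collapses toward zero
#' for effects of no practical size. The robust test divides F by a variance
#' inflation factor VIF = max(1, M/n0), where M is the number of estimates
#' and n0 a reference sample size, and evaluates it on (k-1, min(M, n0) - k)
#' degrees of freedom. For M <= n0 it coincides with [moment_anova()]. The
#' exact inflation factor is a documented, pluggable construction chosen to
#' counteract p-value collapse at large M while never changing small-M
#' results.
#'
#' @inheritParams moment_anova
#' @param n0 Reference sample size (default 100).
#' @return List like [moment_anova()], plus `vif`.
#' @export
robust_moment_anova <- function(table, moment = c("mean", "variance",
                                                  "skewness", "kurtosis"),
                                n0 = 100) {
  moment <- match.arg(moment)
  std <- moment_anova(table, moment)
  vif <- max(1, std$M / n0)
  df2 <- min(std$M, n0) - std$k
  f_r <- std$statistic / vif
  p <- if (std$degenerate && std$statistic == 0) 1
       else stats::pf(f_r, std$k - 1L, df2, lower.tail = FALSE)
  list(statistic = f_r, p_value = p, df = c(std$k - 1L, df2),
       M = std$M, k = std$k, vif = vif, degenerate = std$degenerate)
}

#' Batch-effect diagnostics report
#'
#' Standardizes the supplied matrix (pooled location-scale fit on the given
#' design), computes sample-level and gene-level moment tables, and runs the
#' standard and robust F tests on each of the four moments, yielding the
#' 4 x 2 x 2 grid of p-values. A recommendation is derived from the robust
#' p-values at level `alpha`: significant variance differences call for
#' mean/variance adjustment; mean differences alone for mean-only; otherwise
#' no adjustment is indicated.
#'
#' @param Y Gene-by-sample matrix (raw or previously adjusted).
#' @param design A [study_design()].
#' @param adjustment_label Label recorded in the report (e.g. "None",
#'   "Mean-only", "Mean/variance").
#' @param alpha Significance level for the recommendation.
#' @param n0 Robust-test reference size.
#' @return Object of class `diagnostics_report`: `table` (data frame with
#'   level, moment, statistic, p_value, statistic_robust, p_value_robust),
#'   `label`, `alpha`, `n0`, `recommendation`.
#' @export
batch_diagnostics <- function(Y, design, adjustment_label = "None",
                              alpha = 0.05, n0 = 100) {
  fit <- fit_location_scale(Y, design, mode = "pooled")
  moments <- c("mean", "variance", "skewness", "kurtosis")
  rows <- list()
  for (level in c("sample", "gene")) {
    tab <- compute_moments(fit, level)
    for (m in moments) {
      std <- tryCatch(moment_anova(tab, m),
                      insufficient_observations_error = function(e) NULL)
      rob <- if (is.null(std)) NULL else robust_moment_anova(tab, m, n0 = n0)
      rows[[paste(level, m)]] <- data.frame(
        level = level, moment = m,
        statistic = if (is.null(std)) NA_real_ else std$statistic,
        p_value = if (is.null(std)) NA_real_ else std$p_value,
        statistic_robust = if (is.null(rob)) NA_real_ else rob$statistic,
        p_value_robust = if (is.null(rob)) NA_real_ else rob$p_value)
    }
  }
  table <- do.call(rbind, c(rows, make.row.names = FALSE))
  p_rob <- table$p_value_robust
  sig <- !is.na(p_rob) & p_rob < alpha
  var_sig <- any(sig[table$moment == "variance"])
  mean_sig <- any(sig[table$moment == "mean"])
  recommendation <- if (var_sig) "mean/variance"
                    else if (mean_sig) "mean-only"
                    else "no adjustment indicated"
  structure(list(table = table, label = adjustment_label, alpha = alpha,
                 n0 = n0, recommendation = recommendation),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, digits = 4, ...) {
  cat(sprintf("Batch-effect diagnostics (adjustment: %s)\n", x$label))
  tab <- x$table
  tab$statistic <- signif(tab$statistic, digits)
  tab$p_value <- signif(tab$p_value, digits)
  tab$statistic_robust <- signif(tab$statistic_robust, digits)
  tab$p_value_robust <- signif(tab$p_value_robust, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("Recommendation (alpha = %g): %s\n", x$alpha, x$recommendation))
  invisible(x)
}

#' Serialize diagnostics reports
#'
#' Writes one or several reports as a wide TSV (one row per adjustment
#' state, 16 p-value columns: level x moment x {standard, robust}) and/or a
#' versioned JSON document.
#'
#' @param reports A `diagnostics_report` or list of them.
#' @param tsv,json Output paths (either may be NULL).
#' @return Invisibly, the wide data frame written to the TSV.
#' @export
write_diagnostics <- function(reports, tsv = NULL, json = NULL) {
  if (inherits(reports, "diagnostics_report")) reports <- list(reports)
  wide <- do.call(rbind, lapply(reports, function(r) {
    tab <- r$table
    vals <- c(tab$p_value, tab$p_value_robust)
    names(vals) <- c(paste(tab$level, tab$moment, "standard", sep = "_"),
                     paste(tab$level, tab$moment, "robust", sep = "_"))
    cbind(data.frame(adjustment = r$label,
                     recommendation = r$recommendation),
          as.data.frame(as.list(vals)))
  }))
  if (!is.null(tsv)) {
    utils::write.table(wide, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    doc <- list(schema_version = "1.0",
                reports = lapply(reports, function(r) {
                  list(adjustment = r$label, alpha = r$alpha, n0 = r$n0,
                       recommendation = r$recommendation, tests = r$table)
                }))
    jsonlite::write_json(doc, json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(wide)
}
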