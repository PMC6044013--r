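#' Fit the per-gene location-scale model and standardize the data
#'
#' For each gene g the model is
#' \deqn{Y_{ijg} = \alpha_g + X_{ij} \beta_g + \gamma_{ig} + \delta_{ig} \epsilon_{ijg}}
#' with batch i, sample j, covariate design X, additive batch effect
#' \eqn{\gamma} and multiplicative batch effect \eqn{\delta}. Ordinary least
#' squares on the full design (batch indicators plus covariates) yields batch
#' means and covariate coefficients per gene; the data are then standardized
#' to \deqn{Z_{ijg} = (Y_{ijg} - \hat\alpha_g - X_{ij}\hat\beta_g)/\hat\sigma_g.}
#'
#' In `pooled` mode \eqn{\hat\alpha_g} is the sample-size-weighted average of
#' the batch means (weights \eqn{n_i/N}) and \eqn{\hat\sigma^2_g} the mean
#' squared residual over all N samples (denominator N, matching the unit
#' variance of the standardized scale rather than unbiasedness). In
#' `reference` mode \eqn{\hat\alpha_g} is the reference-batch mean,
#' \eqn{\hat\beta_g} still comes from the all-sample joint fit (so covariate
#' effects remain estimable when a condition is absent from the reference),
#' and \eqn{\hat\sigma^2_g} is the mean squared residual over reference-batch
#' samples only.
#'
#' @param Y Gene-by-sample numeric matrix (see [expression_matrix()]).
#' @param design A [study_design()]; `reference` mode requires its
#'   `reference_batch`.
#' @param mode `"pooled"` or `"reference"`.
#' @return An object of class `standardized_fit` with elements `alpha`,
#'   `beta`, `sigma`, `Z`, `stand_mean`, `mode`, `batch`, `reference_batch`.
#' @export
fit_location_scale <- function(Y, design, mode = c("pooled", "reference")) {
  mode <- match.arg(mode)
  Y <- expression_matrix(Y)
  X <- build_design_matrix(design, ncol(Y))
  batch <- design$batch
  k <- nlevels(batch)
  N <- ncol(Y)
  n_i <- tabulate(batch)

  B <- solve(crossprod(X), crossprod(X, t(Y)))   # p x G coefficients
  batch_means <- B[seq_len(k), , drop = FALSE]

  if (mode == "reference") {
    if (is.null(design$reference_batch)) {
      bfx_error("reference mode requires design$reference_batch", "parse_error")
    }
    r <- match(design$reference_batch, levels(batch))
    idx_r <- which(batch == levels(batch)[r])
    if (length(idx_r) < 2L) {
      bfx_error("reference batch needs at least 2 samples",
                "singleton_batch_error")
    }
    alpha <- batch_means[r, ]
    resid_r <- Y[, idx_r, drop = FALSE] - t(X[idx_r, , drop = FALSE] %*% B)
    sigma2 <- rowMeans(resid_r^2)
  } else {
    alpha <- drop(crossprod(n_i / N, batch_means))
    resid <- Y - t(X %*% B)
    sigma2 <- rowMeans(resid^2)
  }

  tol <- 1e-8 * (max(abs(Y)) + 1)
  sigma <- sqrt(sigma2)
  if (any(sigma < tol)) {
    bad <- rownames(Y)[sigma < tol]
    bfx_error(sprintf(
      "%d gene(s) with (near-)zero residual scale: %s%s. Drop them and refit.",
      length(bad), paste(utils::head(bad, 5), collapse = ", "),
      if (length(bad) > 5) ", ..." else ""),
      "zero_variance_gene_error", list(genes = bad))
  }

  beta <- if (ncol(X) > k) B[-seq_len(k), , drop = FALSE] else NULL
  stand_mean <- matrix(alpha, nrow(Y), N, dimnames = dimnames(Y))
  if (!is.null(beta)) {
    stand_mean <- stand_mean + t(X[, -seq_len(k), drop = FALSE] %*% beta)
  }
  Z <- (Y - stand_mean) / sigma

  structure(list(alpha = alpha, beta = beta, sigma = sigma, Z = Z,
                 stand_mean = stand_mean, mode = mode, batch = batch,
                 reference_batch = design$reference_batch,
                 n_batches = n_i),
            class = "standardized_fit")
}

#' @export
print.standardized_fit <- function(x, ...) {
  cat(sprintf("standardized_fit (%s mode): %d genes x %d samples, %d batches\n",
              x$mode, nrow(x$Z), ncol(x$Z), nlevels(x$batch)))
  invisible(x)
}
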