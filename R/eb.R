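#' Raw per-batch batch-effect estimates from standardized data
#'
#' \eqn{\hat\gamma_{ig}} is the mean of Z over the samples of batch i for
#' gene g; \eqn{\hat\delta^2_{ig}} the unbiased (n_i - 1 denominator)
#' variance. Genes whose within-batch variance is exactly zero are replaced
#' by the batch's smallest positive \eqn{\hat\delta^2} times 1e-3 with a
#' warning, preserving extreme-shrinkage behavior instead of dividing by
#' zero.
#'
#' @param fit A [fit_location_scale()] result.
#' @param variance Estimate multiplicative effects? `FALSE` for mean-only
#'   adjustment: \eqn{\hat\delta^2 \equiv 1} and singleton batches are
#'   allowed.
#' @return List with `gamma_hat` and `delta2_hat`, both batch x gene.
#' @export
estimate_batch_effects <- function(fit, variance = TRUE) {
  stopifnot(inherits(fit, "standardized_fit"))
  Z <- fit$Z
  batch <- fit$batch
  lev <- levels(batch)
  G <- nrow(Z)

  gamma_hat <- t(vapply(lev, function(l) {
    rowMeans(Z[, batch == l, drop = FALSE])
  }, numeric(G)))

  if (!variance) {
    delta2_hat <- matrix(1, length(lev), G, dimnames = dimnames(gamma_hat))
    return(list(gamma_hat = gamma_hat, delta2_hat = delta2_hat))
  }

  n_i <- tabulate(batch)
  if (any(n_i < 2L)) {
    bfx_error(sprintf("batch(es) %s have a single sample; variance-adjusting modes need n_i >= 2",
                      paste(lev[n_i < 2L], collapse = ", ")),
              "singleton_batch_error")
  }
  delta2_hat <- t(vapply(seq_along(lev), function(i) {
    Zi <- Z[, batch == lev[i], drop = FALSE]
    rowSums((Zi - gamma_hat[i, ])^2) / (n_i[i] - 1)
  }, numeric(G)))
  dimnames(delta2_hat) <- dimnames(gamma_hat)

  if (any(delta2_hat == 0)) {
    for (i in seq_along(lev)) {
      zero <- delta2_hat[i, ] == 0
      if (any(zero)) {
        pos <- delta2_hat[i, !zero]
        if (length(pos) == 0L) {
          bfx_error(sprintf("all genes constant within batch %s", lev[i]),
                    "degenerate_prior_error")
        }
        delta2_hat[i, zero] <- min(pos) * 1e-3
        bfx_warning(sprintf(
          "batch %s: %d gene(s) constant within batch; delta^2 floored at %.3g",
          lev[i], sum(zero), min(pos) * 1e-3), "zero_within_batch_variance")
      }
    }
  }
  list(gamma_hat = gamma_hat, delta2_hat = delta2_hat)
}

#' Method-of-moments empirical Bayes hyperpriors
#'
#' The additive effects \eqn{\hat\gamma_{ig}} are assumed drawn, per batch,
#' from a normal hyper-distribution with mean `gamma_bar` and variance
#' `tau2_bar` (cross-gene mean and unbiased variance). The multiplicative
#' effects \eqn{\hat\delta^2_{ig}} are assumed inverse-gamma; with cross-gene
#' mean V and unbiased variance S2 the method-of-moments shape/scale are
#' \deqn{\lambda = (2 S^2 + V^2)/S^2, \quad \theta = (V S^2 + V^3)/S^2.}
#'
#' @param gamma_hat,delta2_hat Batch x gene estimates from
#'   [estimate_batch_effects()].
#' @param variance Fit the inverse-gamma prior for \eqn{\delta^2}? Set
#'   `FALSE` for mean-only adjustment (lambda/theta reported as NA).
#' @param allow_degenerate If `TRUE`, batches whose \eqn{\hat\delta^2} are
#'   identical across genes get NA lambda/theta (no shrinkage downstream)
#'   instead of an error.
#' @return Data frame with one row per batch: `batch`, `gamma_bar`,
#'   `tau2_bar`, `lambda`, `theta`.
#' @export
fit_hyperpriors <- function(gamma_hat, delta2_hat, variance = TRUE,
                            allow_degenerate = FALSE) {
  k <- nrow(gamma_hat)
  gamma_bar <- rowMeans(gamma_hat)
  tau2_bar <- apply(gamma_hat, 1, stats::var)
  if (variance) {
    V <- rowMeans(delta2_hat)
    S2 <- apply(delta2_hat, 1, stats::var)
    # degenerate up to numerical noise from the least-squares residuals
    S2[S2 < (1e-8 * V)^2] <- 0
    if (any(S2 == 0) && !allow_degenerate) {
      bfx_error(sprintf(
        "batch(es) %s: delta^2 identical across genes; cannot fit the inverse-gamma prior",
        paste(rownames(gamma_hat)[S2 == 0], collapse = ", ")),
        "degenerate_prior_error")
    }
    lambda <- ifelse(S2 == 0, NA_real_, (2 * S2 + V^2) / S2)
    theta <- ifelse(S2 == 0, NA_real_, (V * S2 + V^3) / S2)
  } else {
    lambda <- theta <- rep(NA_real_, k)
  }
  data.frame(batch = rownames(gamma_hat) %||% as.character(seq_len(k)),
             gamma_bar = gamma_bar, tau2_bar = tau2_bar,
             lambda = lambda, theta = theta, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Posterior (shrunken) batch-effect estimates
#'
#' Variance modes iterate the conditional posterior means to a fixed point:
#' \deqn{\gamma^*_{ig} = (n_i \tau^2_i \hat\gamma_{ig} + \delta^{*2}_{ig}
#'   \bar\gamma_i) / (n_i \tau^2_i + \delta^{*2}_{ig})}
#' \deqn{\delta^{*2}_{ig} = (\theta_i + \tfrac12 \sum_j (Z_{ijg} -
#'   \gamma^*_{ig})^2) / (n_i/2 + \lambda_i - 1)}
#' initialized at the raw estimates, stopping when the maximum absolute
#' relative change falls below `conv`. Mean-only mode uses the closed form
#' \eqn{\gamma^* = (n_i \tau^2 \hat\gamma + \bar\gamma)/(n_i \tau^2 + 1)}
#' with \eqn{\delta^{*2} \equiv 1}. In reference mode posteriors are computed
#' for non-reference batches only and the reference row is forced to (0, 1).
#' Batches whose `lambda`/`theta` are NA (degenerate inverse-gamma prior)
#' keep \eqn{\delta^{*2} = \hat\delta^2} unshrunken.
#'
#' @param gamma_hat,delta2_hat Raw estimates (batch x gene).
#' @param hyper Hyperprior table from [fit_hyperpriors()].
#' @param fit The [fit_location_scale()] result supplying Z and batches.
#' @param mode `"original"`, `"mean_only"` or `"reference"`.
#' @param conv Relative-change convergence tolerance.
#' @param max_iter Iteration cap before a non-convergence error.
#' @return List with `gamma_star`, `delta2_star` (batch x gene) and
#'   `iterations` per batch.
#' @export
solve_posteriors <- function(gamma_hat, delta2_hat, hyper, fit,
                             mode = c("original", "mean_only", "reference"),
                             conv = 1e-4, max_iter = 100L) {
  mode <- match.arg(mode)
  Z <- fit$Z
  batch <- fit$batch
  lev <- levels(batch)
  n_i <- tabulate(batch)
  k <- length(lev)
  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  iterations <- integer(k)

  if (mode == "mean_only") {
    for (i in seq_len(k)) {
      nt2 <- n_i[i] * hyper$tau2_bar[i]
      gamma_star[i, ] <- (nt2 * gamma_hat[i, ] + hyper$gamma_bar[i]) / (nt2 + 1)
    }
    delta2_star[] <- 1
    return(list(gamma_star = gamma_star, delta2_star = delta2_star,
                iterations = iterations))
  }

  ref <- if (mode == "reference") match(fit$reference_batch, lev) else 0L
  eps <- .Machine$double.eps
  for (i in seq_len(k)) {
    if (i == ref) next
    Zi <- Z[, batch == lev[i], drop = FALSE]
    g_hat <- gamma_hat[i, ]
    if (is.na(hyper$lambda[i])) {    # degenerate prior: no delta shrinkage
      d <- delta2_hat[i, ]
      nt2 <- n_i[i] * hyper$tau2_bar[i]
      gamma_star[i, ] <- (nt2 * g_hat + d * hyper$gamma_bar[i]) / (nt2 + d)
      delta2_star[i, ] <- d
      next
    }
    g_old <- g_hat
    d_old <- delta2_hat[i, ]
    nt2 <- n_i[i] * hyper$tau2_bar[i]
    it <- 0L
    repeat {
      g_new <- (nt2 * g_hat + d_old * hyper$gamma_bar[i]) / (nt2 + d_old)
      sum2 <- rowSums((Zi - g_new)^2)
      d_new <- (hyper$theta[i] + 0.5 * sum2) / (n_i[i] / 2 + hyper$lambda[i] - 1)
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), eps),
                    abs(d_new - d_old) / pmax(d_old, eps))
      g_old <- g_new
      d_old <- d_new
      it <- it + 1L
      if (change < conv) break
      if (it >= max_iter) {
        bfx_error(sprintf("EB posterior iteration for batch %s did not converge in %d iterations",
                          lev[i], max_iter), "non_convergence_error")
      }
    }
    gamma_star[i, ] <- g_old
    delta2_star[i, ] <- d_old
    iterations[i] <- it
  }
  if (ref > 0L) {
    gamma_star[ref, ] <- 0
    delta2_star[ref, ] <- 1
  }
  list(gamma_star = gamma_star, delta2_star = delta2_star,
       iterations = iterations)
}

#' Invert the location-scale model with shrunken batch effects
#'
#' \deqn{Y^*_{ijg} = \hat\sigma_g (Z_{ijg} - \gamma^*_{ig}) /
#'   \sqrt{\delta^{*2}_{ig}} + \hat\alpha_g + X_{ij}\hat\beta_g.}
#' In mean-only mode \eqn{\delta^{*2} \equiv 1}, so only means shift. In
#' reference mode the reference-batch columns of the output are restored by
#' copying the input, guaranteeing bit-identity of the reference batch.
#'
#' @param Y Original expression matrix.
#' @param fit The [fit_location_scale()] result used to build the model.
#' @param model A `batch_effect_model` (see [combat()]) or a list with
#'   `gamma_star`, `delta2_star`, `mode`.
#' @return Adjusted matrix, same shape and dimnames as `Y`.
#' @export
apply_adjustment <- function(Y, fit, model) {
  Y <- expression_matrix(Y)
  stopifnot(identical(dim(Y), dim(fit$Z)))
  batch <- fit$batch
  lev <- levels(batch)
  adj <- fit$Z
  for (i in seq_along(lev)) {
    idx <- batch == lev[i]
    adj[, idx] <- (adj[, idx, drop = FALSE] - model$gamma_star[i, ]) /
      sqrt(model$delta2_star[i, ])
  }
  out <- adj * fit$sigma + fit$stand_mean
  if (model$mode == "reference") {
    idx <- batch == fit$reference_batch
    out[, idx] <- Y[, idx]    # copy, never recompute: bit-stable reference
  }
  out
}

#' Empirical Bayes batch adjustment (original, mean-only, reference)
#'
#' Composes the full pipeline: location-scale fit and standardization, raw
#' batch-effect estimation, method-of-moments hyperpriors, posterior
#' shrinkage, and adjustment. `original` removes additive and multiplicative
#' batch effects against a pooled background; `mean_only` removes only
#' additive effects and preserves within-batch variances exactly;
#' `reference` adjusts every batch to the mean/variance profile of
#' `design$reference_batch` and returns that batch unchanged.
#'
#' @param Y Gene-by-sample matrix of log-scale expression.
#' @param design A [study_design()].
#' @param mode Adjustment mode.
#' @param conv,max_iter Convergence control for [solve_posteriors()].
#' @return An object of class `combat_adjustment`: list with `adjusted`
#'   (matrix), `model` (class `batch_effect_model`: raw and posterior
#'   estimates plus hyperpriors), and `fit` (the `standardized_fit`).
#' @export
combat <- function(Y, design, mode = c("original", "mean_only", "reference"),
                   conv = 1e-4, max_iter = 100L) {
  mode <- match.arg(mode)
  if (nlevels(design$batch) < 2L) {
    bfx_error("only one batch present: nothing to adjust", "single_batch_error")
  }
  if (mode == "reference" && is.null(design$reference_batch)) {
    bfx_error("mode = 'reference' requires design$reference_batch",
              "parse_error")
  }
  variance <- mode != "mean_only"
  if (variance && any(tabulate(design$batch) < 2L)) {
    bfx_error("variance-adjusting modes require >= 2 samples per batch; use mean_only",
              "singleton_batch_error")
  }

  fit <- fit_location_scale(Y, design,
                            mode = if (mode == "reference") "reference" else "pooled")
  est <- estimate_batch_effects(fit, variance = variance)
  hyper <- fit_hyperpriors(est$gamma_hat, est$delta2_hat, variance = variance,
                           allow_degenerate = TRUE)
  if (variance) {
    # the reference batch's delta^2 is identically 1 by construction of the
    # standardization; its (discarded) prior is legitimately degenerate
    check <- setdiff(seq_len(nrow(est$gamma_hat)),
                     match(design$reference_batch %||% "",
                           levels(design$batch), nomatch = 0L))
    if (anyNA(hyper$lambda[check])) {
      bfx_warning(sprintf(
        "batch(es) %s: delta^2 identical across genes; falling back to unshrunken delta^2",
        paste(hyper$batch[check][is.na(hyper$lambda[check])], collapse = ", ")),
        "degenerate_prior_fallback")
    }
  }
  post <- solve_posteriors(est$gamma_hat, est$delta2_hat, hyper, fit,
                           mode = mode, conv = conv, max_iter = max_iter)
  model <- structure(list(gamma_hat = est$gamma_hat,
                          delta2_hat = est$delta2_hat,
                          hyper = hyper,
                          gamma_star = post$gamma_star,
                          delta2_star = post$delta2_star,
                          iterations = post$iterations,
                          mode = mode),
                     class = "batch_effect_model")
  adjusted <- apply_adjustment(expression_matrix(Y), fit, model)
  structure(list(adjusted = adjusted, model = model, fit = fit),
            class = "combat_adjustment")
}

#' @export
print.batch_effect_model <- function(x, ...) {
  cat(sprintf("batch_effect_model (%s): %d batches x %d genes\n",
              x$mode, nrow(x$gamma_hat), ncol(x$gamma_hat)))
  print(x$hyper)
  invisible(x)
}

#' @export
print.combat_adjustment <- function(x, ...) {
  cat(sprintf("combat_adjustment (%s mode): %d genes x %d samples\n",
              x$model$mode, nrow(x$adjusted), ncol(x$adjusted)))
  cat(sprintf("  EB iterations per batch: %s\n",
              paste(x$model$iterations, collapse = ", ")))
  invisible(x)
}
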