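#' Multivariable MR fit
#'
#' Weighted regression of outcome betas on exposure *and* mediator betas
#' jointly, without intercept, weights `1/se_y^2`:
#' `beta_y_j = theta_D beta_x_j + theta_M beta_m_j + e_j`. The exposure
#' coefficient is the direct effect conditional on the mediators; each
#' mediator coefficient is the effect of the mediator on the outcome. SEs use
#' the same multiplicative random-effects inflation as [mr_ivw()]. With all
#' mediator betas zero the exposure coefficient reduces exactly to the
#' univariable IVW estimate. A conditional instrument-strength diagnostic is
#' reported for each regressor: the weighted F-like statistic of its betas
#' after projecting out the other regressors.
#'
#' @param set an `instrument_set` with at least one mediator column
#'   (`beta_<name>` / `se_<name>`, as produced by [harmonize()] with
#'   `mediators=`).
#' @param mediators which mediators to include (default: all carried by the
#'   set).
#' @param weight_mode `"multiplicative_random"` (default) or `"fixed"`.
#' @return an `mr_estimate` (method `"Multivariable IVW"`) for the exposure
#'   direct effect, with extras `mediator_estimates` (named vector),
#'   `mediator_se`, `conditional_F` (named, exposure first),
#'   `condition_number`.
#' @export
mvmr_fit <- function(set, mediators = mediator_names(set),
                     weight_mode = c("multiplicative_random", "fixed")) {
  weight_mode <- match.arg(weight_mode)
  if (is.null(mediators) || length(mediators) == 0)
    stop_("mvmr_fit needs at least one mediator column")
  cols <- paste0("beta_", mediators)
  miss <- setdiff(cols, names(set))
  if (length(miss)) stop_("instrument set lacks mediator column(s): ",
                          paste(miss, collapse = ", "))
  check_set(set, length(mediators) + 2, "multivariable MR")
  X <- cbind(beta_x = set$beta_x,
             as.matrix(set[, cols, drop = FALSE]))
  colnames(X) <- c("exposure", mediators)
  # an identically-zero mediator column is uninformative (and singular):
  # drop it, which reduces the fit to the nested model without that mediator
  zero_col <- c(FALSE, vapply(mediators, function(m)
    all(set[[paste0("beta_", m)]] == 0), logical(1)))
  if (any(zero_col)) {
    message("dropping mediator(s) with all-zero betas: ",
            paste(colnames(X)[zero_col], collapse = ", "))
    X <- X[, !zero_col, drop = FALSE]
    mediators <- setdiff(colnames(X), "exposure")
  }
  w <- 1 / set$se_y^2
  kappa_x <- kappa(sqrt(w) * X, exact = TRUE)
  if (!is.finite(kappa_x) || kappa_x > 1e8)
    stop_("collinear exposure/mediator betas (condition number ",
          signif(kappa_x, 3), ")")
  n <- nrow(set); p <- ncol(X)
  XtWX <- crossprod(X * sqrt(w))
  coefs <- drop(solve(XtWX, crossprod(X, w * set$beta_y)))
  rss <- sum(w * (set$beta_y - drop(X %*% coefs))^2)
  infl <- if (weight_mode == "multiplicative_random")
    max(1, sqrt(rss / (n - p))) else 1
  V <- solve(XtWX) * infl^2
  se <- sqrt(diag(V))

  # conditional instrument strength: residual weighted sum of squares of each
  # regressor after projecting out the others, scaled per SNP (F-like)
  cond_F <- vapply(seq_len(p), function(j) {
    others <- X[, -j, drop = FALSE]
    r <- if (ncol(others)) {
      stats::lm.wfit(others, X[, j], w)$residuals
    } else X[, j]
    sum(w * r^2) / n
  }, numeric(1))
  names(cond_F) <- colnames(X)

  new_mr_estimate("Multivariable IVW", coefs[1], se[1], n,
                  heterogeneity = NULL,
                  extra = list(mediator_estimates = coefs[-1],
                               mediator_se = se[-1],
                               mediator_p = z_pvalue(coefs[-1] / se[-1]),
                               conditional_F = cond_F,
                               condition_number = kappa_x,
                               vcov = V, weight_mode = weight_mode,
                               mediators = mediators))
}

#' Total / direct / mediated effect decomposition
#'
#' Difference-method mediation on summary statistics: the *total* effect is
#' the univariable IVW estimate on the mediator-covered SNP set, the *direct*
#' effect is the multivariable-MR exposure coefficient on the identical SNPs,
#' and the *mediated* effect is their difference (`total = direct + mediated`
#' holds identically). The mediated-effect SE comes from a seeded parametric
#' bootstrap jointly perturbing all betas at their reported SEs; a
#' delta-method cross-check (independence approximation) is also returned.
#'
#' @param set an `instrument_set` with mediator columns.
#' @param mediators mediators to adjust for (default all).
#' @param n_boot bootstrap replicates for the mediated-effect SE (default
#'   1000).
#' @param seed bootstrap seed.
#' @param weight_mode passed to [mr_ivw()] / [mvmr_fit()].
#' @return a `mediation_result`: list with `total`, `direct` (both
#'   `mr_estimate`), `mediated`, `mediated_se`, `mediated_ci`, `mediated_p`,
#'   `prop_mediated`, `mediated_se_delta`, `n_snps`.
#' @export
mediation_decompose <- function(set, mediators = mediator_names(set),
                                n_boot = 1000, seed = 1L,
                                weight_mode = "multiplicative_random") {
  total <- mr_ivw(set, weight_mode = weight_mode)
  direct <- mvmr_fit(set, mediators = mediators, weight_mode = weight_mode)
  mediated <- total$estimate - direct$estimate

  cols <- paste0("beta_", mediators)
  n <- nrow(set)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    pert <- set
    pert$beta_x <- stats::rnorm(n, set$beta_x, set$se_x)
    pert$beta_y <- stats::rnorm(n, set$beta_y, set$se_y)
    for (i in seq_along(cols)) {
      se_col <- paste0("se_", mediators[i])
      pert[[cols[i]]] <- stats::rnorm(n, set[[cols[i]]], set[[se_col]])
    }
    tot_b <- mr_ivw(pert, weight_mode = weight_mode)$estimate
    dir_b <- mvmr_fit(pert, mediators = mediators,
                      weight_mode = weight_mode)$estimate
    tot_b - dir_b
  }, numeric(1))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  med_se <- stats::sd(boot)
  med_se_delta <- sqrt(total$se^2 + direct$se^2) # independence approximation

  structure(list(total = total, direct = direct,
                 mediated = mediated, mediated_se = med_se,
                 mediated_ci = mediated + c(-1.96, 1.96) * med_se,
                 mediated_p = z_pvalue(mediated / med_se),
                 prop_mediated = if (abs(total$estimate) > 1e-12)
                   mediated / total$estimate else NA_real_,
                 mediated_se_delta = med_se_delta,
                 n_snps = nrow(set), n_boot = n_boot, seed = seed,
                 mediators = mediators),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, digits = 4, ...) {
  cat("Mediation decomposition (difference method) over",
      x$n_snps, "SNPs\n")
  cat(sprintf("  Total effect:    %.4f (SE %.4f), HR/OR %.3f [%.3f, %.3f]\n",
              x$total$estimate, x$total$se, x$total$exp_estimate,
              x$total$exp_ci_lower, x$total$exp_ci_upper))
  cat(sprintf("  Direct effect:   %.4f (SE %.4f), HR/OR %.3f [%.3f, %.3f]\n",
              x$direct$estimate, x$direct$se, x$direct$exp_estimate,
              x$direct$exp_ci_lower, x$direct$exp_ci_upper))
  cat(sprintf("  Mediated effect: %.4f (bootstrap SE %.4f, p = %.3g)\n",
              x$mediated, x$mediated_se, x$mediated_p))
  if (is.finite(x$prop_mediated %||% NA))
    cat(sprintf("  Proportion mediated: %.2f\n", x$prop_mediated))
  invisible(x)
}
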