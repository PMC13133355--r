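#' Per-SNP Wald ratio estimates
#'
#' The single-instrument causal estimate `beta_y / beta_x` per SNP with the
#' first-order delta-method SE `se_y / |beta_x|`. SNPs with `beta_x == 0` are
#' excluded (message). Ratios are invariant to joint allele re-orientation.
#'
#' @param set an `instrument_set` (or data frame with `beta_x`, `se_x`,
#'   `beta_y`, `se_y`).
#' @return data frame with `variant_id` (if present), `ratio`, `se`.
#' @export
ratio_estimates <- function(set) {
  check_set(set, 1, "ratio_estimates")
  zero <- set$beta_x == 0
  if (any(zero)) {
    message(sum(zero), " SNP(s) with zero exposure beta excluded from ratios")
    set <- set[!zero, , drop = FALSE]
  }
  if (nrow(set) == 0) stop_("no SNPs left after excluding zero exposure betas")
  data.frame(variant_id = set$variant_id %||% seq_len(nrow(set)),
             ratio = set$beta_y / set$beta_x,
             se = set$se_y / abs(set$beta_x),
             stringsAsFactors = FALSE)
}

# Tukey-biweight IRLS for (optionally weighted) regression; X may omit
# the intercept for through-origin fits. Returns coefficients and the
# robustness weights at convergence.
tukey_irls <- function(X, y, w, c_tune = 4.685, tol = 1e-8, maxit = 100) {
  X <- as.matrix(X)
  fit <- stats::lm.wfit(X, y, w)
  beta <- fit$coefficients
  for (it in seq_len(maxit)) {
    r <- y - drop(X %*% beta)
    rs <- r * sqrt(w)                        # standardized by reported precision
    s <- stats::median(abs(rs)) / 0.6745
    if (s <= 0) s <- stats::sd(rs)
    if (!is.finite(s) || s <= 0) break
    u <- rs / (c_tune * s)
    rw <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (all(rw == 0)) stop_("robust fit degenerate: all observations downweighted")
    fit <- stats::lm.wfit(X, y, w * rw)
    delta <- max(abs(fit$coefficients - beta))
    beta <- fit$coefficients
    if (delta < tol * max(1, max(abs(beta)))) break
  }
  list(coefficients = beta, robust_weights = rw, scale = s)
}

# Q contributions at a given theta (weights 1/se_y^2) and the penalization
# multiplier min(1, k * p_j) of the cited estimator family.
penal_weights <- function(set, theta, k = 20) {
  w <- 1 / set$se_y^2
  q_j <- w * (set$beta_y - theta * set$beta_x)^2
  p_j <- stats::pchisq(q_j, df = 1, lower.tail = FALSE)
  pmin(1, k * p_j)
}

#' Inverse-variance weighted (IVW) estimator
#'
#' Weighted regression of outcome betas on exposure betas through the origin
#' with weights `1/se_y^2`: the closed form
#' `theta = sum(w bx by) / sum(w bx^2)`. Variants:
#' \describe{
#'   \item{fixed}{SE `1/sqrt(sum(w bx^2))`.}
#'   \item{multiplicative_random}{SE inflated by `max(1, sqrt(Q/df))` — the
#'     default, since heterogeneity among instruments is the rule.}
#' }
#' `penalized` multiplies weights by `min(1, 20 p_j)` where `p_j` is the
#' chi-square(1) upper-tail probability of SNP j's Q contribution at the
#' initial estimate; `robust` replaces least squares by Tukey-biweight IRLS
#' (tuning constant 4.685).
#'
#' @param set an `instrument_set`.
#' @param weight_mode `"multiplicative_random"` (default) or `"fixed"`.
#' @param penalized,robust logical flags.
#' @return an `mr_estimate` with a `heterogeneity` element (see
#'   [mr_heterogeneity()]).
#' @export
mr_ivw <- function(set, weight_mode = c("multiplicative_random", "fixed"),
                   penalized = FALSE, robust = FALSE) {
  weight_mode <- match.arg(weight_mode)
  check_set(set, 2, "IVW")
  w <- 1 / set$se_y^2
  theta0 <- sum(w * set$beta_x * set$beta_y) / sum(w * set$beta_x^2)
  if (penalized) {
    w <- w * penal_weights(set, theta0)
    if (all(w == 0)) stop_("all weights zero after penalization")
  }
  if (robust) {
    rf <- tukey_irls(matrix(set$beta_x, ncol = 1), set$beta_y, w)
    theta <- unname(rf$coefficients[1])
    w_eff <- w * rf$robust_weights
  } else {
    theta <- sum(w * set$beta_x * set$beta_y) / sum(w * set$beta_x^2)
    w_eff <- w
  }
  se_fixed <- sqrt(1 / sum(w_eff * set$beta_x^2))
  n <- nrow(set)
  het <- mr_heterogeneity(set, theta)
  se <- if (weight_mode == "multiplicative_random") {
    rss <- sum(w_eff * (set$beta_y - theta * set$beta_x)^2)
    se_fixed * max(1, sqrt(rss / (n - 1)))
  } else se_fixed
  label <- paste0(if (penalized) "Penalized " else "",
                  if (robust) "Robust " else "", "IVW")
  new_mr_estimate(trimws(label), theta, se, n, heterogeneity = het,
                  extra = list(weight_mode = weight_mode,
                               penalized = penalized, robust = robust))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas *with* an intercept
#' (weights `1/se_y^2`). The slope is the pleiotropy-adjusted causal estimate
#' under the InSIDE assumption; the intercept estimates the average
#' directional pleiotropic effect, with its own SE and p-value. SNPs are
#' re-oriented so every exposure beta is positive before fitting (required for
#' the intercept to be interpretable). SEs use the multiplicative
#' random-effects inflation `max(1, sqrt(RSS/(n-2)))` by default.
#'
#' @inheritParams mr_ivw
#' @return an `mr_estimate` with `intercept`, `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(set, weight_mode = c("multiplicative_random", "fixed"),
                     penalized = FALSE, robust = FALSE) {
  weight_mode <- match.arg(weight_mode)
  check_set(set, 3, "MR-Egger")
  neg <- set$beta_x < 0
  bx <- abs(set$beta_x)
  by <- ifelse(neg, -set$beta_y, set$beta_y)
  w <- 1 / set$se_y^2
  X <- cbind(1, bx)
  fit0 <- stats::lm.wfit(X, by, w)
  if (penalized) {
    # Q contributions of the Egger fit at the initial coefficients
    r0 <- by - drop(X %*% fit0$coefficients)
    p_j <- stats::pchisq(w * r0^2, df = 1, lower.tail = FALSE)
    w <- w * pmin(1, 20 * p_j)
    if (all(w == 0)) stop_("all weights zero after penalization")
  }
  if (robust) {
    rf <- tukey_irls(X, by, w)
    coefs <- rf$coefficients
    w_eff <- w * rf$robust_weights
  } else {
    coefs <- stats::lm.wfit(X, by, w)$coefficients
    w_eff <- w
  }
  n <- nrow(set)
  XtWX <- crossprod(X * sqrt(w_eff))
  V_fixed <- solve(XtWX)
  rss <- sum(w_eff * (by - drop(X %*% coefs))^2)
  infl <- if (weight_mode == "multiplicative_random") max(1, sqrt(rss / (n - 2))) else 1
  V <- V_fixed * infl^2
  label <- paste0(if (penalized) "Penalized " else "",
                  if (robust) "Robust " else "", "MR-Egger")
  new_mr_estimate(trimws(label), coefs[2], sqrt(V[2, 2]), n,
                  intercept = coefs[1], intercept_se = sqrt(V[1, 1]),
                  heterogeneity = mr_heterogeneity(
                    data.frame(beta_x = bx, se_x = set$se_x,
                               beta_y = by - coefs[1], se_y = set$se_y), coefs[2]),
                  extra = list(weight_mode = weight_mode,
                               penalized = penalized, robust = robust))
}

#' Median-based MR estimators
#'
#' Simple median (unweighted median of per-SNP Wald ratios), weighted median
#' (50th weighted percentile of ratios with weights proportional to
#' `1/SE(ratio)^2`, linear interpolation across the cumulative weight
#' function), and penalized weighted median (weights first multiplied by
#' `min(1, 20 p_j)` from the Q contributions at the weighted-median estimate).
#' The weighted median is consistent when valid instruments carry more than
#' half the weight. SEs by seeded parametric bootstrap: betas are resampled at
#' their reported SEs and the estimator recomputed.
#'
#' @param set an `instrument_set`.
#' @param variant `"simple"`, `"weighted"` or `"penalized_weighted"`.
#' @param n_boot bootstrap replicates (default 1000; < 100 warns).
#' @param seed seed for the bootstrap.
#' @return an `mr_estimate`.
#' @export
mr_median <- function(set, variant = c("weighted", "simple", "penalized_weighted"),
                      n_boot = 1000, seed = 1L) {
  variant <- match.arg(variant)
  check_set(set, 3, "median MR")
  if (n_boot < 100) warning("n_boot < 100: bootstrap SE will be unstable")

  point <- function(bx, by, se_y) {
    r <- by / bx
    se_r <- se_y / abs(bx)
    w <- switch(variant,
                simple = rep(1, length(r)),
                weighted = 1 / se_r^2,
                penalized_weighted = {
                  w0 <- 1 / se_r^2
                  th0 <- weighted_quantile(r, w0, 0.5)
                  q_j <- (by - th0 * bx)^2 / se_y^2
                  p_j <- stats::pchisq(q_j, df = 1, lower.tail = FALSE)
                  w0 * pmin(1, 20 * p_j)
                })
    if (sum(w) == 0) w <- rep(1, length(r))
    weighted_quantile(r, w, 0.5)
  }
  est <- point(set$beta_x, set$beta_y, set$se_y)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  n <- nrow(set)
  boot <- vapply(seq_len(n_boot), function(b) {
    point(stats::rnorm(n, set$beta_x, set$se_x),
          stats::rnorm(n, set$beta_y, set$se_y),
          set$se_y)
  }, numeric(1))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  se <- stats::sd(boot)
  label <- switch(variant, simple = "Simple median", weighted = "Weighted median",
                  penalized_weighted = "Penalized weighted median")
  new_mr_estimate(label, est, se, n,
                  extra = list(n_boot = n_boot, boot_seed = seed))
}

#' Cochran's Q heterogeneity statistics
#'
#' `Q = sum_j w_j (beta_y_j - theta * beta_x_j)^2` with `w_j = 1/se_y_j^2`,
#' df `n - 1`, p-value from the chi-square reference. `I^2 = max(0, (Q-df)/Q)`
#' with the Higgins-Thompson test-based confidence interval.
#'
#' @param set an `instrument_set`.
#' @param theta causal-effect value at which Q is evaluated; default the
#'   fixed-effect IVW estimate.
#' @return list of class `mr_heterogeneity`: `Q`, `df`, `p_value`, `I2`,
#'   `I2_ci` (length 2), `contributions` (per SNP, summing to Q).
#' @export
mr_heterogeneity <- function(set, theta = NULL) {
  check_set(set, 2, "heterogeneity")
  w <- 1 / set$se_y^2
  if (is.null(theta))
    theta <- sum(w * set$beta_x * set$beta_y) / sum(w * set$beta_x^2)
  contrib <- w * (set$beta_y - theta * set$beta_x)^2
  Q <- sum(contrib)
  df <- nrow(set) - 1
  I2 <- max(0, (Q - df) / Q)
  # Higgins & Thompson test-based CI for H, transformed to I^2
  if (df >= 2) {
    lnH <- 0.5 * log(max(Q / df, 1e-12))
    se_lnH <- if (Q > df) {
      0.5 * (log(Q) - log(df)) / (sqrt(2 * Q) - sqrt(2 * df - 1))
    } else {
      sqrt(1 / (2 * (df - 1)) * (1 - 1 / (3 * (df - 1)^2)))
    }
    H_ci <- pmax(exp(lnH + c(-1, 1) * 1.96 * se_lnH), 1)
    I2_ci <- (H_ci^2 - 1) / H_ci^2
  } else {
    I2_ci <- c(0, 1) # CI undefined with a single degree of freedom
  }
  structure(list(Q = Q, df = df,
                 p_value = stats::pchisq(Q, df, lower.tail = FALSE),
                 I2 = I2, I2_ci = I2_ci, contributions = contrib,
                 theta = theta),
            class = "mr_heterogeneity")
}

#' @export
print.mr_heterogeneity <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.2f on %d df (p = %.3g); I2 = %.1f%% [%.1f%%, %.1f%%]\n",
              x$Q, x$df, x$p_value, 100 * x$I2, 100 * x$I2_ci[1], 100 * x$I2_ci[2]))
  invisible(x)
}

#' Radial-MR outlier detection and removal
#'
#' Fits the radial IVW model (regression of `beta_y/se_y` on `beta_x/se_y`
#' through the origin, identical point estimate to fixed-effect IVW) and
#' compares each SNP's Q contribution to the chi-square(1) reference. SNPs
#' with upper-tail p below `alpha_level` are flagged and removed, optionally
#' iterating until no new outliers emerge.
#'
#' @param set an `instrument_set`.
#' @param alpha_level per-SNP significance threshold (default 0.05).
#' @param iterate if `TRUE` (default), repeat removal until stable.
#' @return list: `outliers` (variant IDs), `set` (trimmed `instrument_set`),
#'   `Q` (radial global Q of the final fit), `contributions` (final per-SNP).
#' @export
radial_outliers <- function(set, alpha_level = 0.05, iterate = TRUE) {
  check_set(set, 3, "radial MR")
  keep <- rep(TRUE, nrow(set))
  repeat {
    cur <- set[keep, , drop = FALSE]
    w <- 1 / cur$se_y^2
    theta <- sum(w * cur$beta_x * cur$beta_y) / sum(w * cur$beta_x^2)
    contrib <- w * (cur$beta_y - theta * cur$beta_x)^2
    p_j <- stats::pchisq(contrib, df = 1, lower.tail = FALSE)
    new_out <- p_j < alpha_level
    if (all(new_out)) stop_("all SNPs flagged as radial outliers")
    if (!any(new_out) || !iterate) {
      if (any(new_out)) keep[keep][new_out] <- FALSE
      break
    }
    keep[keep][new_out] <- FALSE
  }
  cur <- set[keep, , drop = FALSE]
  w <- 1 / cur$se_y^2
  theta <- sum(w * cur$beta_x * cur$beta_y) / sum(w * cur$beta_x^2)
  contrib <- w * (cur$beta_y - theta * cur$beta_x)^2
  trimmed <- if (inherits(set, "instrument_set")) set_subset(set, keep)
  else set[keep, , drop = FALSE]
  ids <- set$variant_id %||% seq_len(nrow(set))
  list(outliers = ids[!keep], set = trimmed, Q = sum(contrib),
       contributions = contrib, theta = theta)
}

#' Compare two MR estimates
#'
#' Two-sided z-test for a difference between estimates on the same scale,
#' assuming independence: `z = (a - b) / sqrt(se_a^2 + se_b^2)`.
#'
#' @param a,b `mr_estimate` objects.
#' @return list with `z`, `p_value`, `difference`, `se`.
#' @export
compare_estimates <- function(a, b) {
  stopifnot(inherits(a, "mr_estimate"), inherits(b, "mr_estimate"))
  d <- a$estimate - b$estimate
  se <- sqrt(a$se^2 + b$se^2)
  z <- d / se
  list(z = z, p_value = z_pvalue(z), difference = d, se = se)
}
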