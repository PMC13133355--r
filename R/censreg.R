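#' Weighted right-censored Gaussian (Tobit-type) linear regression
#'
#' Fits a linear model for a right-censored outcome by maximizing the weighted
#' censored-normal log-likelihood: event rows contribute the normal density,
#' right-censored rows the upper-tail probability, each raised to its sampling
#' weight. Standard errors come from a cluster-level sandwich estimator (score
#' contributions summed within cluster, small-sample factor `G/(G-1)` with `G`
#' clusters), so that dependence among relatives in family-based cohorts and
#' weighted-cohort sampling weights are both accounted for. With no censoring,
#' unit weights and one cluster per row the fit reduces to ordinary least
#' squares.
#'
#' This is the instrument-validation model for carrier cohorts: regress the
#' (censored) age at natural menopause on the standardized genetic score plus
#' birth-cohort indicators, weights from [compute_cohort_weights()], clusters
#' by family. Fully observed traits (age at menarche) use the same fit with
#' `status` all 1.
#'
#' @param formula model formula; the response may be a two-column matrix
#'   `cbind(time, status)` (status 1 = observed event, 0 = right-censored), or
#'   supply `status` separately.
#' @param data data frame.
#' @param status optional vector of event indicators when the response is a
#'   plain numeric (default: all observed).
#' @param weights optional positive sampling weights (e.g.
#'   `compute_cohort_weights()$weight`).
#' @param cluster optional cluster identifiers (e.g. family ID); default one
#'   cluster per observation.
#' @param control list: `maxit` (default 200), `reltol` on the gradient norm
#'   (default 1e-8).
#' @return an object of class `censreg` with `coefficients`, `sigma` (residual
#'   scale), `vcov` (cluster-robust), `vcov_naive`, `se`, `n_events`,
#'   `n_censored`, `n_clusters`, `logLik`, `convergence` diagnostics.
#' @export
censreg <- function(formula, data, status = NULL, weights = NULL,
                    cluster = NULL, control = list()) {
  ctrl <- utils::modifyList(list(maxit = 200L, reltol = 1e-8), control)
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (is.matrix(y) && ncol(y) == 2) {
    status_v <- y[, 2]
    y <- y[, 1]
  } else {
    status_v <- if (is.null(status)) rep(1, length(y)) else status
  }
  n <- length(y)
  stopifnot(length(status_v) == n)
  status_v <- as.numeric(status_v)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w <= 0) || any(!is.finite(w)))
    stop_("weights must be positive, finite, one per observation")
  cl <- if (is.null(cluster)) seq_len(n) else cluster
  if (length(cl) != n) stop_("cluster must have one entry per observation")
  if (sum(status_v) < 2) stop_("need at least 2 observed events")
  if (all(status_v == 0)) stop_("all observations censored")
  if (qr(X)$rank < ncol(X)) stop_("design matrix is rank deficient")

  ev <- status_v == 1
  # start from OLS on the uncensored rows
  ols <- stats::lm.wfit(X[ev, , drop = FALSE], y[ev], w[ev])
  b0 <- ols$coefficients
  b0[is.na(b0)] <- 0
  s0 <- sqrt(sum(w[ev] * ols$residuals^2) / sum(w[ev]))
  if (!is.finite(s0) || s0 <= 0) s0 <- stats::sd(y)
  par0 <- c(b0, log_sigma = log(s0))
  p <- ncol(X)

  negll <- function(par) {
    beta <- par[seq_len(p)]; sig <- exp(par[p + 1])
    z <- (y - drop(X %*% beta)) / sig
    ll <- ifelse(ev, stats::dnorm(z, log = TRUE) - log(sig),
                 stats::pnorm(z, lower.tail = FALSE, log.p = TRUE))
    -sum(w * ll)
  }
  grad_mat <- function(par) {
    beta <- par[seq_len(p)]; sig <- exp(par[p + 1])
    z <- (y - drop(X %*% beta)) / sig
    lambda <- exp(stats::dnorm(z, log = TRUE) -
                    stats::pnorm(z, lower.tail = FALSE, log.p = TRUE))
    db <- ifelse(ev, z, lambda) / sig     # d loglik / d (x beta) per row
    dls <- ifelse(ev, z^2 - 1, lambda * z) # d loglik / d log sigma per row
    cbind(X * (w * db), log_sigma = w * dls)
  }
  neggr <- function(par) -colSums(grad_mat(par))

  opt <- stats::optim(par0, negll, neggr, method = "BFGS",
                      control = list(maxit = ctrl$maxit, reltol = 1e-14),
                      hessian = TRUE)
  gnorm <- sqrt(sum(neggr(opt$par)^2))
  if (opt$convergence != 0 && gnorm > sqrt(ctrl$reltol))
    stop_("censored regression did not converge (gradient norm ", signif(gnorm, 3), ")")

  beta <- opt$par[seq_len(p)]
  names(beta) <- colnames(X)
  sigma <- unname(exp(opt$par[p + 1]))

  H <- opt$hessian                        # observed information of -loglik
  bread <- tryCatch(solve(H), error = function(e)
    stop_("singular information matrix in censored regression"))
  U <- grad_mat(opt$par)                  # per-observation scores
  Ug <- rowsum(U, group = cl)             # summed within cluster
  G <- nrow(Ug)
  meat <- crossprod(Ug) * G / (G - 1)
  V <- bread %*% meat %*% bread
  Vb <- V[seq_len(p), seq_len(p), drop = FALSE]
  dimnames(Vb) <- list(names(beta), names(beta))
  Vn <- bread[seq_len(p), seq_len(p), drop = FALSE]
  dimnames(Vn) <- dimnames(Vb)

  structure(list(coefficients = beta, sigma = sigma,
                 vcov = Vb, vcov_naive = Vn, se = sqrt(diag(Vb)),
                 logLik = -opt$value, n = n, n_events = sum(ev),
                 n_censored = sum(!ev), n_clusters = G,
                 gradient_norm = gnorm, iterations = opt$counts[["function"]],
                 converged = gnorm <= sqrt(ctrl$reltol) || opt$convergence == 0,
                 fitted.values = drop(X %*% beta),
                 residuals = y - drop(X %*% beta),
                 y = y, status = status_v, weights = w,
                 call = match.call(), terms = attr(mf, "terms")),
            class = "censreg")
}

#' @export
coef.censreg <- function(object, ...) object$coefficients

#' @export
vcov.censreg <- function(object, ...) object$vcov

#' @export
logLik.censreg <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients) + 1, class = "logLik")
}

#' @export
residuals.censreg <- function(object, ...) object$residuals

#' @export
fitted.censreg <- function(object, ...) object$fitted.values

#' @export
predict.censreg <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  X <- stats::model.matrix(stats::delete.response(object$terms), newdata)
  drop(X %*% object$coefficients)
}

#' @export
confint.censreg <- function(object, parm, level = 0.95, ...) {
  est <- object$coefficients
  if (missing(parm)) parm <- names(est)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(est[parm] - zq * object$se[parm], est[parm] + zq * object$se[parm])
  colnames(out) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  out
}

#' @export
print.censreg <- function(x, digits = 4, ...) {
  cat("Right-censored Gaussian regression (cluster-robust)\n")
  cat(sprintf("  %d observations: %d events, %d censored; %d clusters\n",
              x$n, x$n_events, x$n_censored, x$n_clusters))
  print(round(x$coefficients, digits))
  cat("Residual scale (sigma):", signif(x$sigma, digits), "\n")
  invisible(x)
}

#' @export
summary.censreg <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Robust SE` = object$se,
               z = z, `Pr(>|z|)` = z_pvalue(z),
               `L95` = object$coefficients - 1.96 * object$se,
               `U95` = object$coefficients + 1.96 * object$se)
  structure(list(coefficients = tab, sigma = object$sigma,
                 n = object$n, n_events = object$n_events,
                 n_censored = object$n_censored, n_clusters = object$n_clusters,
                 logLik = object$logLik, converged = object$converged,
                 call = object$call),
            class = "summary.censreg")
}

#' @export
print.summary.censreg <- function(x, digits = 4, ...) {
  cat("Right-censored Gaussian regression, cluster-robust sandwich SEs\n")
  cat(sprintf("n = %d (%d events, %d censored), clusters = %d, logLik = %.2f\n",
              x$n, x$n_events, x$n_censored, x$n_clusters, x$logLik))
  stats::printCoefmat(x$coefficients[, 1:4, drop = FALSE], digits = digits)
  cat("sigma =", signif(x$sigma, digits), "\n")
  invisible(x)
}
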