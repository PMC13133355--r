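#' Construct an MR estimate object
#' @noRd
new_mr_estimate <- function(method, estimate, se, n_snps,
                            intercept = NULL, intercept_se = NULL,
                            heterogeneity = NULL, extra = list()) {
  estimate <- unname(estimate); se <- unname(se)
  if (!is.null(intercept)) {
    intercept <- unname(intercept); intercept_se <- unname(intercept_se)
  }
  ci <- ci_fields(estimate, se)
  out <- c(list(method = method, estimate = estimate, se = se,
                n_snps = n_snps), ci,
           list(intercept = intercept, intercept_se = intercept_se,
                intercept_p = if (!is.null(intercept))
                  z_pvalue(intercept / intercept_se) else NULL,
                heterogeneity = heterogeneity),
           extra)
  structure(out, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("%s: estimate = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$method, x$estimate, x$se, x$ci_lower, x$ci_upper, x$p_value))
  cat(sprintf("  exp scale: %.3f [%.3f, %.3f]; n_snps = %d\n",
              x$exp_estimate, x$exp_ci_lower, x$exp_ci_upper, x$n_snps))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept = %.4g (SE %.4g), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  invisible(x)
}

#' @export
coef.mr_estimate <- function(object, ...) {
  out <- c(estimate = object$estimate)
  if (!is.null(object$intercept)) out <- c(out, intercept = object$intercept)
  out
}

#' @export
confint.mr_estimate <- function(object, parm, level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- matrix(c(object$estimate - zq * object$se,
                  object$estimate + zq * object$se), 1,
                dimnames = list("estimate", c("lower", "upper")))
  if (!is.null(object$intercept))
    out <- rbind(out, intercept = c(object$intercept - zq * object$intercept_se,
                                    object$intercept + zq * object$intercept_se))
  out
}

#' @export
summary.mr_estimate <- function(object, ...) object

#' One-row summary suitable for report tables
#' @param est an `mr_estimate`.
#' @return data frame with method, estimate, exponentiated scale, CI and p.
#' @export
mr_row <- function(est) {
  data.frame(method = est$method, estimate = est$estimate, se = est$se,
             exp_estimate = est$exp_estimate,
             L95 = est$exp_ci_lower, U95 = est$exp_ci_upper,
             p = est$p_value, n_snps = est$n_snps,
             intercept = est$intercept %||% NA_real_,
             intercept_p = est$intercept_p %||% NA_real_,
             stringsAsFactors = FALSE)
}

check_set <- function(set, min_snps = 2, method = "MR") {
  stopifnot(inherits(set, "data.frame"))
  need <- c("beta_x", "se_x", "beta_y", "se_y")
  miss <- setdiff(need, names(set))
  if (length(miss)) stop_("instrument set lacks column(s): ",
                          paste(miss, collapse = ", "))
  if (nrow(set) < min_snps)
    stop_(method, " requires at least ", min_snps, " SNPs (got ", nrow(set), ")")
  invisible(set)
}
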