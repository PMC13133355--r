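# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_ <- function(...) stop(..., call. = FALSE)

#' Weighted quantile with linear interpolation across the cumulative weight
#' function (Bowden-style weighted-median convention: the j-th order statistic
#' sits at cumulative probability (S_j - w_j/2) / S_n).
#' @noRd
weighted_quantile <- function(x, w, p = 0.5) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  q <- (cw - w / 2) / sum(w)
  if (p <= q[1]) return(x[1])
  if (p >= q[length(q)]) return(x[length(x)])
  stats::approx(q, x, xout = p, ties = "ordered")$y
}

# DNA complement for strand resolution during harmonization
comp_allele <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# two-sided normal p-value
z_pvalue <- function(z) 2 * stats::pnorm(-abs(z))

# 95% CI on the log scale together with exponentiated versions
ci_fields <- function(estimate, se, level = 0.95) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  lo <- estimate - zq * se
  hi <- estimate + zq * se
  list(
    ci_lower = lo, ci_upper = hi,
    exp_estimate = exp(estimate), exp_ci_lower = exp(lo), exp_ci_upper = exp(hi),
    p_value = z_pvalue(estimate / se)
  )
}

#' Split-chain potential scale reduction factor (Rhat) and a crude effective
#' sample size for a draws matrix (iterations x chains).
#' @noRd
split_rhat <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub); nn <- nrow(sub)
  mu <- colMeans(sub)
  B <- nn * stats::var(mu)
  W <- mean(apply(sub, 2, stats::var))
  vhat <- (nn - 1) / nn * W + B / nn
  sqrt(vhat / W)
}

ess_basic <- function(draws) {
  # pooled autocorrelation-based ESS (Geyer initial positive sequence, truncated)
  x <- as.vector(draws)
  n <- length(x)
  ac <- stats::acf(x, lag.max = min(200, n - 1), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(ac)) {
    if (ac[k] < 0.05) break
    s <- s + ac[k]
  }
  n / (1 + 2 * s)
}
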