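#' Scenario for simulated two-sample MR summary statistics
#'
#' Defines the generative model for per-SNP GWAS summary statistics under a
#' linear causal model with configurable horizontal pleiotropy. True per-allele
#' exposure effects are drawn half-normal (effect alleles oriented
#' trait-increasing, as published instrument lists are); true outcome effects
#' are `theta * beta_x + alpha`, where `alpha` is the direct (pleiotropic)
#' effect of the variant on the outcome. Reported estimates are drawn around
#' the truth at the reported standard errors, which are log-uniform within the
#' given ranges and independent of effect size.
#'
#' Pleiotropy modes:
#' \describe{
#'   \item{none}{all `alpha = 0` (every instrument valid).}
#'   \item{balanced}{`alpha ~ N(0, pleiotropy_sd^2)` for a fraction
#'     `prop_invalid` of SNPs (InSIDE holds, zero mean).}
#'   \item{directional}{`alpha ~ N(pleiotropy_mean, pleiotropy_sd^2)` for the
#'     invalid fraction (InSIDE holds, nonzero mean: biases IVW, not Egger).}
#'   \item{correlated}{`alpha = rho * scale(beta_x) * pleiotropy_sd + residual`,
#'     inducing dependence between instrument strength and direct effect
#'     (violates InSIDE; the regime targeted by the horseshoe estimator).}
#' }
#'
#' @param n_snps number of independent instruments (>= 3).
#' @param theta true causal effect, outcome units (log HR/OR) per exposure unit.
#' @param exposure_beta_sd SD of the half-normal true per-allele exposure effects.
#' @param min_instrument_z minimum instrument strength in SE units: true
#'   exposure effects are `min_instrument_z * se_x + |N(0, exposure_beta_sd)|`,
#'   so every instrument clears the genome-wide discovery threshold, as
#'   published instrument lists do (default 5.45, the z-value of p = 5e-8).
#'   Set to 0 for untruncated half-normal effects.
#' @param se_x_range,se_y_range ranges (length 2, strictly positive) for
#'   reported exposure / outcome standard errors.
#' @param pleiotropy_mode one of `"none"`, `"balanced"`, `"directional"`,
#'   `"correlated"`.
#' @param pleiotropy_sd SD of the direct effects.
#' @param pleiotropy_mean mean direct effect (directional mode).
#' @param prop_invalid fraction of SNPs with a nonzero direct effect.
#' @param rho correlation between instrument strength and direct effect
#'   (correlated mode).
#' @param mediator_spec optional list describing a mediator trait:
#'   `theta_m` (outcome units per mediator unit), `snp_m_sd` (SD of direct
#'   SNP-to-mediator effects), `x_to_m` (mediator units per exposure unit, the
#'   exposure-to-mediator path), `se_m_range` (reported mediator SE range).
#' @param eaf_range effect-allele frequency range, strictly inside (0, 1).
#' @param flip_fraction fraction of SNPs whose outcome/mediator rows are
#'   presented with effect/other alleles swapped (beta negated, eaf
#'   complemented), to exercise harmonization.
#' @param strand_fraction fraction of non-palindromic SNPs whose outcome rows
#'   are reported on the opposite strand.
#' @param palindromic_fraction fraction of SNPs assigned A/T or C/G alleles.
#' @param seed RNG seed.
#' @return an object of class `sumstats_scenario`.
#' @seealso [gen_twosample_sumstats()]
#' @export
sumstats_scenario <- function(n_snps = 100,
                              theta = 0,
                              exposure_beta_sd = 0.1,
                              min_instrument_z = 5.45,
                              se_x_range = c(0.005, 0.015),
                              se_y_range = c(0.01, 0.03),
                              pleiotropy_mode = c("none", "balanced",
                                                  "directional", "correlated"),
                              pleiotropy_sd = 0.01,
                              pleiotropy_mean = 0,
                              prop_invalid = 0.3,
                              rho = 0.7,
                              mediator_spec = NULL,
                              eaf_range = c(0.05, 0.95),
                              flip_fraction = 0.3,
                              strand_fraction = 0.1,
                              palindromic_fraction = 0.1,
                              seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (n_snps < 3) stop_("n_snps must be >= 3")
  if (prop_invalid < 0 || prop_invalid > 1) stop_("prop_invalid must lie in [0, 1]")
  for (r in list(se_x_range, se_y_range)) {
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2])
      stop_("SE ranges must be strictly positive length-2 increasing vectors")
  }
  if (eaf_range[1] <= 0 || eaf_range[2] >= 1 || eaf_range[1] > eaf_range[2])
    stop_("eaf_range must lie strictly inside (0, 1)")
  if (!is.null(mediator_spec)) {
    stopifnot(is.list(mediator_spec))
    mediator_spec <- utils::modifyList(
      list(theta_m = 0, snp_m_sd = 0.05, x_to_m = 0, se_m_range = c(0.003, 0.01)),
      mediator_spec)
  }
  if (min_instrument_z < 0) stop_("min_instrument_z must be non-negative")
  structure(
    list(n_snps = as.integer(n_snps), theta = theta,
         exposure_beta_sd = exposure_beta_sd,
         min_instrument_z = min_instrument_z,
         se_x_range = se_x_range, se_y_range = se_y_range,
         pleiotropy_mode = pleiotropy_mode, pleiotropy_sd = pleiotropy_sd,
         pleiotropy_mean = pleiotropy_mean, prop_invalid = prop_invalid,
         rho = rho, mediator_spec = mediator_spec, eaf_range = eaf_range,
         flip_fraction = flip_fraction, strand_fraction = strand_fraction,
         palindromic_fraction = palindromic_fraction, seed = as.integer(seed)),
    class = "sumstats_scenario")
}

# allele pairs drawn for non-palindromic SNPs (any unordered non-complementary pair)
.nonpal_pairs <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
.pal_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Generate two-sample MR summary statistics with known truth
#'
#' Draws per-SNP exposure, outcome and (optionally) mediator association tables
#' under the generative model in the scenario, together with a truth record.
#' Draw order is fixed (alleles, frequencies, reported standard errors, true
#' effects, pleiotropy, sampling noise, presentation flips) so that fixtures
#' are stable for a given seed.
#'
#' @param scenario a [sumstats_scenario()].
#' @return list with elements `exposure`, `outcome`, `mediator` (or `NULL`),
#'   each an `assoc_table` data frame with columns `variant_id`, `chr`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`; and `truth`, a list
#'   holding `theta`, per-SNP true effects `beta_x`, direct effects `alpha`,
#'   validity flags `valid`, and the mediator paths when simulated.
#' @export
gen_twosample_sumstats <- function(scenario) {
  stopifnot(inherits(scenario, "sumstats_scenario"))
  s <- scenario
  set.seed(s$seed)
  n <- s$n_snps
  ids <- sprintf("rs%06d", seq_len(n))

  # 1. alleles
  pal <- stats::runif(n) < s$palindromic_fraction
  pair_idx_np <- sample.int(nrow(.nonpal_pairs), n, replace = TRUE)
  pair_idx_p <- sample.int(nrow(.pal_pairs), n, replace = TRUE)
  ea <- ifelse(pal, .pal_pairs[pair_idx_p, 1], .nonpal_pairs[pair_idx_np, 1])
  oa <- ifelse(pal, .pal_pairs[pair_idx_p, 2], .nonpal_pairs[pair_idx_np, 2])

  # 2. frequencies
  eaf <- stats::runif(n, s$eaf_range[1], s$eaf_range[2])

  # 3. reported SEs, log-uniform within range, independent of effect size
  rlunif <- function(k, r) exp(stats::runif(k, log(r[1]), log(r[2])))
  se_x <- rlunif(n, s$se_x_range)
  se_y <- rlunif(n, s$se_y_range)

  # 4. true exposure effects: effect allele oriented trait-increasing, and
  # every instrument above its own discovery threshold
  beta_x <- s$min_instrument_z * se_x + abs(stats::rnorm(n, 0, s$exposure_beta_sd))

  # 5. pleiotropic direct effects
  alpha <- numeric(n)
  invalid <- rep(FALSE, n)
  if (s$pleiotropy_mode != "none" && s$prop_invalid > 0) {
    n_inv <- round(s$prop_invalid * n)
    invalid[sample.int(n, n_inv)] <- TRUE
    if (s$pleiotropy_mode == "balanced") {
      alpha[invalid] <- stats::rnorm(n_inv, 0, s$pleiotropy_sd)
    } else if (s$pleiotropy_mode == "directional") {
      alpha[invalid] <- stats::rnorm(n_inv, s$pleiotropy_mean, s$pleiotropy_sd)
    } else { # correlated: alpha depends on instrument strength (InSIDE violated)
      zx <- as.numeric(scale(beta_x[invalid]))
      if (n_inv == 1) zx <- 0
      alpha[invalid] <- s$pleiotropy_sd *
        (s$rho * zx + sqrt(max(0, 1 - s$rho^2)) * stats::rnorm(n_inv))
    }
  }

  # 6. mediator paths
  med <- NULL
  beta_m <- NULL
  if (!is.null(s$mediator_spec)) {
    ms <- s$mediator_spec
    beta_m0 <- stats::rnorm(n, 0, ms$snp_m_sd)
    beta_m <- beta_m0 + ms$x_to_m * beta_x
    beta_y_true <- s$theta * beta_x + ms$theta_m * beta_m + alpha
  } else {
    beta_y_true <- s$theta * beta_x + alpha
  }

  # 7. sampling noise around truth
  bhat_x <- stats::rnorm(n, beta_x, se_x)
  bhat_y <- stats::rnorm(n, beta_y_true, se_y)

  mk_tab <- function(beta, se, eaf_col) {
    structure(
      data.frame(variant_id = ids, chr = rep("1", n), pos = seq_len(n) * 1e5,
                 effect_allele = ea, other_allele = oa, eaf = eaf_col,
                 beta = beta, se = se, stringsAsFactors = FALSE),
      class = c("assoc_table", "data.frame"))
  }
  exposure <- mk_tab(bhat_x, se_x, eaf)

  if (!is.null(s$mediator_spec)) {
    se_m <- rlunif(n, s$mediator_spec$se_m_range)
    bhat_m <- stats::rnorm(n, beta_m, se_m)
    mediator <- mk_tab(bhat_m, se_m, eaf)
  } else {
    mediator <- NULL
  }
  outcome <- mk_tab(bhat_y, se_y, eaf)

  # 8. presentation flips on the outcome (and mediator) tables
  flip <- stats::runif(n) < s$flip_fraction
  strand <- !pal & stats::runif(n) < s$strand_fraction
  present <- function(tab) {
    tab$beta[flip] <- -tab$beta[flip]
    tab$eaf[flip] <- 1 - tab$eaf[flip]
    tmp <- tab$effect_allele[flip]
    tab$effect_allele[flip] <- tab$other_allele[flip]
    tab$other_allele[flip] <- tmp
    tab$effect_allele[strand] <- comp_allele(tab$effect_allele[strand])
    tab$other_allele[strand] <- comp_allele(tab$other_allele[strand])
    tab
  }
  outcome <- present(outcome)
  if (!is.null(mediator)) mediator <- present(mediator)

  truth <- list(theta = s$theta, beta_x = beta_x, alpha = alpha,
                valid = !invalid, variant_id = ids,
                flipped = flip, strand_flipped = strand, palindromic = pal)
  if (!is.null(s$mediator_spec)) {
    truth$beta_m <- beta_m
    truth$theta_m <- s$mediator_spec$theta_m
    truth$x_to_m <- s$mediator_spec$x_to_m
    truth$theta_total <- s$theta + s$mediator_spec$theta_m * s$mediator_spec$x_to_m
  }
  list(exposure = exposure, outcome = outcome, mediator = mediator, truth = truth)
}
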