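#' Scenario for a simulated ascertained carrier cohort
#'
#' Describes a family-based cohort of pathogenic-variant carriers recruited
#' through genetic-testing clinics: a latent reproductive trait (age at
#' natural menopause by default) driven by a standardized genetic score,
#' competing censoring events (risk-reducing surgery, cancer diagnosis, death,
#' interview) and oversampling of affected families, mirroring the structure
#' of clinic-recruited carrier studies.
#'
#' @param n_families number of families sampled into the cohort.
#' @param mean_family_size mean members per family (sizes are
#'   `1 + Poisson(mean_family_size - 1)`).
#' @param gs_true_effect years of trait per population SD of the raw score.
#' @param trait_mean,trait_sd population trait distribution in years
#'   (defaults 51 / 4, an age-at-natural-menopause regime; use 13 / 1.5 for
#'   age at menarche).
#' @param trait one of `"anm"` (right-censored questionnaire phenotype) or
#'   `"aam"` (fully observed).
#' @param family_effect_sd SD of an optional shared family random effect on
#'   the trait (default 0: dependence enters only through the robust
#'   variance, as in the analysis model).
#' @param rrso_prob lifetime probability of risk-reducing
#'   salpingo-oophorectomy; ages drawn uniform on `rrso_age_range`.
#' @param rrso_age_range age range for RRSO (years).
#' @param interview_age_range interview ages, uniform (years).
#' @param death_rate constant annual death hazard before interview.
#' @param admin_censor_age administrative censoring age (years, default 60).
#' @param birth_cohort_probs named probabilities over birth-cohort categories
#'   (defaults to the `<1940`, `1940-1949`, `1950-1959`, `>=1960` bins).
#' @param incidence an [incidence_table()] of age-specific disease incidence
#'   used both to simulate disease and to drive ascertainment.
#' @param oversample_affected ascertainment multiplier: the relative
#'   probability that a family containing at least one affected member is
#'   recruited (1 = simple random sampling).
#' @param seed RNG seed.
#' @return an object of class `cohort_scenario`.
#' @export
cohort_scenario <- function(n_families = 500,
                            mean_family_size = 1.6,
                            gs_true_effect = 1.5,
                            trait_mean = 51, trait_sd = 4,
                            trait = c("anm", "aam"),
                            family_effect_sd = 0,
                            rrso_prob = 0.4,
                            rrso_age_range = c(35, 55),
                            interview_age_range = c(25, 75),
                            death_rate = 0.001,
                            admin_censor_age = 60,
                            birth_cohort_probs = c("<1940" = 0.10,
                                                   "1940-1949" = 0.25,
                                                   "1950-1959" = 0.35,
                                                   ">=1960" = 0.30),
                            incidence = incidence_table(
                              age_lo = c(18, 30, 40, 50, 60),
                              age_hi = c(30, 40, 50, 60, 80),
                              rate = c(0.002, 0.010, 0.020, 0.022, 0.020)),
                            oversample_affected = 2,
                            seed = 1L) {
  trait <- match.arg(trait)
  if (trait_sd <= 0) stop_("trait_sd must be positive")
  if (admin_censor_age <= 18) stop_("admin_censor_age must exceed the minimum adult age")
  if (abs(gs_true_effect) >= trait_sd)
    stop_("gs_true_effect must be smaller in magnitude than trait_sd")
  if (any(incidence$rate < 0)) stop_("incidence rates must be non-negative")
  if (abs(sum(birth_cohort_probs) - 1) > 1e-8)
    stop_("birth_cohort_probs must sum to 1")
  structure(list(n_families = as.integer(n_families),
                 mean_family_size = mean_family_size,
                 gs_true_effect = gs_true_effect,
                 trait_mean = trait_mean, trait_sd = trait_sd, trait = trait,
                 family_effect_sd = family_effect_sd,
                 rrso_prob = rrso_prob, rrso_age_range = rrso_age_range,
                 interview_age_range = interview_age_range,
                 death_rate = death_rate,
                 admin_censor_age = admin_censor_age,
                 birth_cohort_probs = birth_cohort_probs,
                 incidence = incidence,
                 oversample_affected = oversample_affected,
                 seed = as.integer(seed)),
            class = "cohort_scenario")
}

# inverse-transform sample of disease age from a piecewise-constant hazard;
# returns Inf when the individual escapes disease before `max_age`
sample_event_age <- function(inc, n, max_age = 80) {
  u <- stats::runif(n)
  target <- -log(u)
  ch_hi <- cum_hazard(inc, inc$age_hi)
  ch_lo <- c(0, ch_hi[-length(ch_hi)])
  age <- rep(Inf, n)
  for (k in seq_len(nrow(inc))) {
    hit <- target > ch_lo[k] & target <= ch_hi[k] & inc$rate[k] > 0
    age[hit] <- inc$age_lo[k] + (target[hit] - ch_lo[k]) / inc$rate[k]
  }
  ifelse(age > max_age, Inf, age)
}

#' Generate an ascertained carrier cohort with questionnaire fields
#'
#' Simulates genotype dosages at the score model's allele frequencies (binomial
#' under Hardy-Weinberg equilibrium), a latent trait linear in the
#' population-standardized raw score, disease onset from the scenario's
#' incidence table, competing censoring events, and the raw questionnaire
#' fields from which [derive_menopause_phenotype()] reconstructs the censored
#' phenotype. Families with at least one affected member are oversampled by
#' the scenario's ascertainment multiplier. Draw order is fixed (family
#' sizes, birth cohorts, dosages, family effects, trait noise, disease ages,
#' RRSO, death, interview ages, ascertainment) so outputs are reproducible
#' byte-for-byte at a given seed.
#'
#' @param scenario a [cohort_scenario()].
#' @param gs_model a [genetic_score_model()] with frequencies for every SNP.
#' @return list with `cohort` (data frame: `id`, `family_id`, `birth_cohort`,
#'   `gene`, dosage columns, `raw_score`, `latent_trait`, `affected`,
#'   questionnaire fields, `aam`) and `truth` (list: `gs_true_effect`,
#'   `theoretical_sd`, per-individual latent traits).
#' @export
gen_carrier_cohort <- function(scenario, gs_model) {
  stopifnot(inherits(scenario, "cohort_scenario"),
            inherits(gs_model, "score_model"))
  if (nrow(gs_model) < 1) stop_("score model must contain at least one SNP")
  if (anyNA(gs_model$eaf)) stop_("score model needs frequencies for every SNP")
  s <- scenario
  set.seed(s$seed)

  # sample a pool larger than needed, then ascertain families
  pool_fams <- ceiling(s$n_families * max(2, s$oversample_affected + 1))
  fam_size <- 1L + stats::rpois(pool_fams, max(0, s$mean_family_size - 1))
  fam_id <- rep(sprintf("F%05d", seq_len(pool_fams)), fam_size)
  n <- length(fam_id)

  birth_cohort <- sample(names(s$birth_cohort_probs), n, replace = TRUE,
                         prob = s$birth_cohort_probs)
  gene <- sample(c("BRCA1", "BRCA2"), n, replace = TRUE)

  k <- nrow(gs_model)
  dos <- matrix(stats::rbinom(n * k, 2L, rep(gs_model$eaf, each = n)), n, k)
  colnames(dos) <- gs_model$variant_id
  raw <- drop(dos %*% gs_model$weight)
  theo_mean <- sum(2 * gs_model$eaf * gs_model$weight)
  theo_sd <- theoretical_sd_effect(gs_model)
  z <- (raw - theo_mean) / theo_sd

  fam_eff <- rep(stats::rnorm(pool_fams, 0, s$family_effect_sd), fam_size)
  resid_sd <- sqrt(max(s$trait_sd^2 - s$gs_true_effect^2 - s$family_effect_sd^2, 1e-6))
  latent <- s$trait_mean + s$gs_true_effect * z + fam_eff +
    stats::rnorm(n, 0, resid_sd)
  aam <- 13 + 0.3 * z + stats::rnorm(n, 0, sqrt(1.5^2 - 0.3^2))
  if (s$trait == "aam") {
    latent <- s$trait_mean + s$gs_true_effect * z + fam_eff +
      stats::rnorm(n, 0, resid_sd)
    aam <- latent
  }

  dx_age <- sample_event_age(s$incidence, n)
  has_rrso <- stats::runif(n) < s$rrso_prob
  rrso_age <- ifelse(has_rrso,
                     stats::runif(n, s$rrso_age_range[1], s$rrso_age_range[2]),
                     NA_real_)
  death_age <- 18 + stats::rexp(n, max(s$death_rate, 1e-12))
  death_age[death_age > 100] <- NA_real_
  interview_age <- stats::runif(n, s$interview_age_range[1],
                                s$interview_age_range[2])
  interview_age <- pmin(interview_age,
                        ifelse(is.na(death_age), Inf, death_age))

  affected <- is.finite(dx_age) & dx_age <= interview_age
  dx_obs <- ifelse(affected, dx_age, NA_real_)

  # questionnaire consistent with latent trait and censoring processes
  first_censor <- pmin(ifelse(is.na(rrso_age), Inf, rrso_age),
                       ifelse(is.na(dx_obs), Inf, dx_obs),
                       interview_age)
  # women report natural menopause whenever it truly preceded every censoring
  # event; the administrative age-60 rule is applied downstream at derivation
  natural <- latent < first_censor
  reason <- rep(NA_character_, n)
  age_lm <- rep(NA_real_, n)
  reason[natural] <- "natural menopause"
  age_lm[natural] <- latent[natural] - 1
  stopped_rrso <- !natural & !is.na(rrso_age) & rrso_age <= interview_age &
    rrso_age < latent
  reason[stopped_rrso] <- "rrso"
  age_lm[stopped_rrso] <- rrso_age[stopped_rrso]
  had_period_past_year <- is.na(reason)

  pool <- data.frame(id = sprintf("I%06d", seq_len(n)), family_id = fam_id,
                     birth_cohort = birth_cohort, gene = gene,
                     stringsAsFactors = FALSE)
  pool <- cbind(pool, as.data.frame(dos))
  pool$raw_score <- raw
  pool$latent_trait <- latent
  pool$affected <- affected
  pool$had_period_past_year <- had_period_past_year
  pool$reason_stopped <- reason
  pool$age_last_menstruation <- age_lm
  pool$age_rrso <- rrso_age
  pool$age_cancer_diagnosis <- dx_obs
  pool$age_interview <- interview_age
  pool$age_death <- death_age
  pool$aam <- aam

  # ascertainment: families with an affected member recruited preferentially
  fam_aff <- tapply(affected, fam_id, any)
  pr <- ifelse(fam_aff, s$oversample_affected, 1)
  take <- sample(names(fam_aff), s$n_families, replace = FALSE,
                 prob = pr / sum(pr))
  cohort <- pool[pool$family_id %in% take, , drop = FALSE]
  rownames(cohort) <- NULL

  list(cohort = cohort,
       truth = list(gs_true_effect = s$gs_true_effect,
                    theoretical_sd = theo_sd,
                    latent_trait = cohort$latent_trait,
                    scenario = s))
}
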