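test_that("identical seeds give byte-identical outputs", {
  scen <- sumstats_scenario(n_snps = 40, theta = 0.02,
                            pleiotropy_mode = "balanced", seed = 77)
  expect_identical(gen_twosample_sumstats(scen), gen_twosample_sumstats(scen))

  cs <- cohort_scenario(n_families = 100, seed = 77)
  gm <- toy_score_model(k = 8, seed = 77)
  expect_identical(gen_carrier_cohort(cs, gm), gen_carrier_cohort(cs, gm))
})

test_that("scenario invariants are enforced", {
  expect_error(sumstats_scenario(n_snps = 2), "n_snps")
  expect_error(sumstats_scenario(prop_invalid = 1.2), "prop_invalid")
  expect_error(sumstats_scenario(se_y_range = c(0, 0.01)), "positive")
  expect_error(sumstats_scenario(eaf_range = c(0, 0.9)), "eaf_range")
  expect_error(cohort_scenario(trait_sd = -1), "trait_sd")
  expect_error(cohort_scenario(admin_censor_age = 10), "admin_censor_age")
})

test_that("null causal effect gives near-zero mean ratio", {
  scen <- sumstats_scenario(n_snps = 100, theta = 0, pleiotropy_mode = "none",
                            seed = 1, flip_fraction = 0, strand_fraction = 0,
                            palindromic_fraction = 0)
  sim <- gen_twosample_sumstats(scen)
  set <- harmonize(sim$exposure, sim$outcome)
  est <- mr_ivw(set)
  expect_lt(abs(est$estimate), 2.5 * est$se)
})

test_that("no-pleiotropy regression of outcome on exposure betas recovers theta", {
  scen <- sumstats_scenario(n_snps = 2000, theta = 0.08,
                            pleiotropy_mode = "none", seed = 2,
                            flip_fraction = 0, strand_fraction = 0,
                            palindromic_fraction = 0)
  sim <- gen_twosample_sumstats(scen)
  fit <- lm(sim$outcome$beta ~ 0 + sim$exposure$beta,
            weights = 1 / sim$outcome$se^2)
  expect_equal(unname(coef(fit)), 0.08, tolerance = 0.02)
})

test_that("directional pleiotropy surfaces in the Egger intercept", {
  ints <- ses <- numeric(30)
  for (r in seq_len(30)) {
    scen <- sumstats_scenario(n_snps = 100, theta = 0.02,
                              pleiotropy_mode = "directional",
                              pleiotropy_mean = 0.01, pleiotropy_sd = 0.002,
                              prop_invalid = 1, seed = 300 + r)
    sim <- gen_twosample_sumstats(scen)
    est <- mr_egger(harmonize(sim$exposure, sim$outcome))
    ints[r] <- est$intercept; ses[r] <- est$intercept_se
  }
  expect_lt(abs(mean(ints) - 0.01), 2 * sd(ints) / sqrt(30))
})

test_that("correlated mode ties direct effects to instrument strength", {
  scen <- sumstats_scenario(n_snps = 500, theta = 0,
                            pleiotropy_mode = "correlated", rho = 0.8,
                            pleiotropy_sd = 0.02, prop_invalid = 0.5, seed = 3)
  sim <- gen_twosample_sumstats(scen)
  tr <- sim$truth
  inv <- !tr$valid
  expect_gt(cor(tr$alpha[inv], tr$beta_x[inv]), 0.5)
  expect_true(all(tr$alpha[tr$valid] == 0))
})

test_that("truth record flags and allele flips are consistent with the tables", {
  scen <- sumstats_scenario(n_snps = 60, theta = 0.05, flip_fraction = 0.5,
                            seed = 4)
  sim <- gen_twosample_sumstats(scen)
  tr <- sim$truth
  swapped <- sim$outcome$effect_allele != sim$exposure$effect_allele &
    sim$outcome$effect_allele %in%
      c(sim$exposure$other_allele, carriermr:::comp_allele(sim$exposure$other_allele))
  expect_equal(sum(tr$flipped), sum(tr$flipped & swapped))
})

test_that("cohort generator: trait SD sanity without ascertainment or censoring", {
  gm <- toy_score_model(k = 15, seed = 41)
  scen <- cohort_scenario(n_families = 4000, oversample_affected = 1,
                          gs_true_effect = 1.5, trait_sd = 4, seed = 41)
  cc <- gen_carrier_cohort(scen, gm)
  expect_equal(sd(cc$cohort$latent_trait), 4, tolerance = 0.15)
  expect_equal(mean(cc$cohort$latent_trait), 51, tolerance = 0.3)
})

test_that("menopause-before-censoring fraction decreases with censor hazards", {
  gm <- toy_score_model(k = 10, seed = 42)
  frac_event <- function(rrso_prob, seed = 42) {
    scen <- cohort_scenario(n_families = 1500, rrso_prob = rrso_prob,
                            seed = seed)
    cc <- gen_carrier_cohort(scen, gm)
    ph <- derive_menopause_phenotype(cc$cohort)
    mean(ph$status == 1 & ph$censor_reason == "natural_menopause", na.rm = TRUE)
  }
  f0 <- frac_event(0); f5 <- frac_event(0.5); f9 <- frac_event(0.9)
  expect_gt(f0, f5)
  expect_gt(f5, f9)
})

test_that("family random effects induce within-family trait correlation", {
  gm <- toy_score_model(k = 10, seed = 43)
  scen <- cohort_scenario(n_families = 1500, family_effect_sd = 2,
                          mean_family_size = 2.5, seed = 43)
  cc <- gen_carrier_cohort(scen, gm)
  ch <- cc$cohort
  fams <- split(ch$latent_trait, ch$family_id)
  fams <- fams[vapply(fams, length, integer(1)) >= 2]
  pairs <- t(vapply(fams, function(v) v[1:2], numeric(2)))
  expect_gt(cor(pairs[, 1], pairs[, 2]), 0.1)
})

test_that("rejected generator inputs error", {
  gm <- toy_score_model(k = 5, seed = 44)
  gm$eaf[2] <- NA
  expect_error(gen_carrier_cohort(cohort_scenario(n_families = 10), gm),
               "frequencies")
})
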