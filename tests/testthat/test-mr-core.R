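test_that("Wald ratios match the closed form and are orientation-invariant", {
  set <- toy_set(beta_x = 0.1, beta_y = 0.05, se_y = 0.02)
  r <- ratio_estimates(set)
  expect_equal(r$ratio, 0.5)
  expect_equal(r$se, 0.2)

  flipped <- toy_set(beta_x = -0.1, beta_y = -0.05, se_y = 0.02)
  expect_equal(ratio_estimates(flipped)$ratio, r$ratio)
  expect_equal(ratio_estimates(flipped)$se, r$se)

  # delta-method SE on a 5-SNP toy set against direct computation
  s5 <- random_set(5, seed = 1)
  r5 <- ratio_estimates(s5)
  expect_equal(r5$se, s5$se_y / abs(s5$beta_x), tolerance = 1e-12)
})

test_that("IVW closed form is exact on a 2-SNP set and matches the WLS oracle", {
  set <- toy_set(beta_x = c(1, 1), beta_y = c(0.5, 0.5), se_y = c(1, 1))
  est <- mr_ivw(set)
  expect_equal(est$estimate, 0.5, tolerance = 1e-12)
  expect_equal(est$heterogeneity$Q, 0, tolerance = 1e-12)
  # with Q <= df the multiplicative inflation floors at 1: fixed == random
  expect_equal(est$se, mr_ivw(set, weight_mode = "fixed")$se, tolerance = 1e-12)

  s <- random_set(50, seed = 2)
  w <- 1 / s$se_y^2
  oracle <- lm(beta_y ~ 0 + beta_x, data = s, weights = w)
  expect_equal(mr_ivw(s, weight_mode = "fixed")$estimate,
               unname(coef(oracle)), tolerance = 1e-10)
})

test_that("IVW recovers a simulated causal effect", {
  scen <- sumstats_scenario(n_snps = 50, theta = log(1.04),
                            pleiotropy_mode = "none", seed = 5)
  sim <- gen_twosample_sumstats(scen)
  set <- harmonize(sim$exposure, sim$outcome)
  est <- mr_ivw(set)
  expect_lt(abs(est$estimate - log(1.04)), 2 * est$se)
})

test_that("Egger recovers slope and intercept exactly on noise-free data", {
  bx <- seq(0.05, 0.5, length.out = 10)
  theta <- 0.3
  set <- toy_set(beta_x = bx, beta_y = theta * bx + 0.01,
                 se_y = rep(0.02, 10))
  est <- mr_egger(set)
  expect_equal(est$estimate, theta, tolerance = 1e-10)
  expect_equal(est$intercept, 0.01, tolerance = 1e-10)
})

test_that("Egger orients exposure betas positive before fitting", {
  bx <- seq(0.05, 0.5, length.out = 12)
  set <- toy_set(beta_x = bx, beta_y = 0.2 * bx + 0.015, se_y = rep(0.02, 12))
  set_f <- set
  idx <- c(2, 7)
  set_f$beta_x[idx] <- -set_f$beta_x[idx]
  set_f$beta_y[idx] <- -set_f$beta_y[idx]
  est <- mr_egger(set); est_f <- mr_egger(set_f)
  expect_equal(est_f$estimate, est$estimate, tolerance = 1e-12)
  expect_equal(est_f$intercept, est$intercept, tolerance = 1e-12)
})

test_that("robust IRLS agrees with the independent M-estimator implementation", {
  skip_if_not_installed("MASS")
  set.seed(3)
  n <- 60
  s <- toy_set(beta_x = abs(rnorm(n, 0, 0.1)), beta_y = NA,
               se_y = runif(n, 0.01, 0.05))
  s$beta_y <- 0.2 * s$beta_x + rnorm(n, 0, s$se_y)
  lev <- which.max(s$beta_x^2 / s$se_y^2) # highest-leverage SNP
  s$beta_y[lev] <- s$beta_y[lev] + 0.5    # one gross outlier
  w <- 1 / s$se_y^2
  est <- mr_ivw(s, robust = TRUE)
  # same through-origin robust regression in the sqrt(w)-transformed space
  rl <- MASS::rlm(sqrt(w) * s$beta_y ~ 0 + I(sqrt(w) * s$beta_x),
                  psi = MASS::psi.bisquare, c = 4.685, maxit = 100)
  expect_equal(est$estimate, unname(coef(rl)), tolerance = 5e-3)
  # and the outlier drags the plain IVW further from the truth
  plain <- mr_ivw(s)
  expect_lt(abs(est$estimate - 0.2), abs(plain$estimate - 0.2))
})

test_that("median estimators: closed forms and breakdown behaviour", {
  set <- toy_set(beta_x = c(1, 1, 1), beta_y = c(1, 2, 3), se_y = c(1, 1, 1))
  est <- mr_median(set, "simple", n_boot = 100)
  expect_equal(est$estimate, 2)

  # one SNP carrying > 50% of the weight dominates the weighted median
  # (equality is approached as its weight share grows, by interpolation)
  set2 <- toy_set(beta_x = rep(1, 4), beta_y = c(0.9, 1, 1.1, 5),
                  se_y = c(1, 1, 1, 0.001))
  est2 <- mr_median(set2, "weighted", n_boot = 100)
  expect_equal(est2$estimate, 5, tolerance = 1e-4)

  # majority-valid scenario: weighted median near truth where the fixed-effect
  # IVW (whose SE ignores the invalid instruments' direct effects) is not
  scen <- sumstats_scenario(n_snps = 80, theta = 0, pleiotropy_mode = "balanced",
                            pleiotropy_sd = 0.3,
                            prop_invalid = 0.3, seed = 6)
  sim <- gen_twosample_sumstats(scen)
  set3 <- harmonize(sim$exposure, sim$outcome)
  wm <- mr_median(set3, "weighted", n_boot = 300, seed = 6)
  ivw <- mr_ivw(set3, weight_mode = "fixed")
  expect_lt(abs(wm$estimate), 2 * wm$se)
  expect_gt(abs(ivw$estimate), 2 * ivw$se)
})

test_that("median bootstrap SE is seeded and reproducible", {
  s <- random_set(30, seed = 7)
  e1 <- mr_median(s, "weighted", n_boot = 200, seed = 42)
  e2 <- mr_median(s, "weighted", n_boot = 200, seed = 42)
  expect_identical(e1$se, e2$se)
  expect_warning(mr_median(s, "weighted", n_boot = 50), "unstable")
})

test_that("heterogeneity: Q decomposition, df, and perfect proportionality", {
  set <- toy_set(beta_x = c(0.1, 0.2, 0.3), beta_y = c(0.05, 0.1, 0.15),
                 se_y = c(0.01, 0.02, 0.03))
  h <- mr_heterogeneity(set)
  expect_equal(h$Q, 0, tolerance = 1e-20)
  expect_equal(h$I2, 0)
  expect_equal(h$df, 2)

  s <- random_set(40, seed = 8)
  h2 <- mr_heterogeneity(s)
  expect_equal(sum(h2$contributions), h2$Q, tolerance = 1e-12)
  expect_equal(h2$df, 39)
  expect_true(h2$I2 >= 0 && h2$I2 < 1)
})

test_that("Q follows its chi-square null distribution", {
  n_rep <- 400
  rej <- 0L
  for (r in seq_len(n_rep)) {
    scen <- sumstats_scenario(n_snps = 30, theta = 0.05,
                              pleiotropy_mode = "none",
                              se_x_range = c(1e-4, 2e-4), seed = 5000 + r,
                              flip_fraction = 0, strand_fraction = 0,
                              palindromic_fraction = 0)
    sim <- gen_twosample_sumstats(scen)
    set <- harmonize(sim$exposure, sim$outcome)
    rej <- rej + (mr_heterogeneity(set)$p_value < 0.05)
  }
  expect_lt(abs(rej / n_rep - 0.05), 1.96 * sqrt(0.05 * 0.95 / n_rep) + 0.005)
})

test_that("radial outlier detection flags injected pleiotropy and decomposes Q", {
  s <- random_set(40, seed = 9)
  s$beta_y <- 0.2 * s$beta_x + rnorm(40, 0, s$se_y) # homogeneous
  rad0 <- radial_outliers(s, alpha_level = 0.001)
  expect_length(rad0$outliers, 0)

  s2 <- s
  s2$beta_y[10] <- s2$beta_y[10] + 10 * s2$se_y[10]
  rad <- radial_outliers(s2, alpha_level = 0.05)
  expect_true(s2$variant_id[10] %in% rad$outliers)
  expect_equal(sum(rad$contributions), rad$Q, tolerance = 1e-10)
  expect_equal(nrow(rad$set) + length(rad$outliers), nrow(s2))
})

test_that("estimate comparison: closed form, symmetry, identity", {
  a <- carriermr:::new_mr_estimate("IVW", 0.04, 0.005, 10)
  b <- carriermr:::new_mr_estimate("IVW", 0.02, 0.008, 10)
  cmp <- compare_estimates(a, b)
  expect_equal(cmp$z, 0.02 / sqrt(0.005^2 + 0.008^2), tolerance = 1e-12)
  expect_equal(round(cmp$z, 2), 2.12)
  expect_equal(cmp$p_value, 0.034, tolerance = 0.001)
  swapped <- compare_estimates(b, a)
  expect_equal(swapped$z, -cmp$z)
  expect_equal(swapped$p_value, cmp$p_value)
  same <- compare_estimates(a, a)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
})

test_that("exponentiated CIs bracket the exponentiated estimate", {
  for (seed in 1:5) {
    s <- random_set(25, seed = 100 + seed)
    for (est in list(mr_ivw(s), mr_egger(s),
                     mr_median(s, "weighted", n_boot = 100, seed = seed))) {
      expect_lt(est$exp_ci_lower, est$exp_estimate)
      expect_gt(est$exp_ci_upper, est$exp_estimate)
      expect_equal(est$exp_estimate, exp(est$estimate))
    }
  }
})

test_that("estimators are invariant to SNP ordering", {
  s <- random_set(35, seed = 11)
  perm <- s[sample(nrow(s)), ]
  expect_equal(mr_ivw(perm)$estimate, mr_ivw(s)$estimate, tolerance = 1e-12)
  expect_equal(mr_egger(perm)$estimate, mr_egger(s)$estimate, tolerance = 1e-12)
  expect_equal(mr_median(perm, "simple", n_boot = 100)$estimate,
               mr_median(s, "simple", n_boot = 100)$estimate, tolerance = 1e-12)
})

test_that("minimum SNP-count preconditions are enforced", {
  s <- random_set(2, seed = 12)
  expect_error(mr_egger(s), "at least 3")
  expect_error(mr_median(s, "simple"), "at least 3")
  expect_error(mr_ivw(s[1, ]), "at least 2")
})
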