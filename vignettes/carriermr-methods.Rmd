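---
title: "Models and methods in carriermr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in carriermr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

carriermr implements a two-sample Mendelian randomization (MR) chain for
studying genetically predicted age at natural menopause (ANM) and age at
menarche (AAM) against breast-cancer risk, with the extra machinery that
*BRCA1*/*BRCA2* carrier cohorts need: censored phenotypes, family clustering,
and ascertainment correction. This vignette records the models, the default
choices and why, and what the synthetic-data tests do and do not establish.

## The MR model

For SNP $j$, let $\hat\beta_{Xj}$ be its per-allele association with the
exposure (years of ANM or AAM) and $\hat\beta_{Yj}$ its per-allele log hazard
(or odds) ratio for breast cancer, with standard error
$se(\hat\beta_{Yj})$. The univariable model is the weighted regression through
the origin

$$\hat\beta_{Yj} = \theta\,\hat\beta_{Xj} + \varepsilon_j,\qquad
\varepsilon_j \sim N(0,\, se(\hat\beta_{Yj})^2),$$

whose weighted-least-squares solution is the IVW estimate
$\hat\theta = \sum w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum w_j
\hat\beta_{Xj}^2$, $w_j = 1/se(\hat\beta_{Yj})^2$. `exp(theta)` is the hazard
ratio per year of the exposure. The multivariable variant adds mediator
columns (e.g. per-allele BMI effects):
$\hat\beta_{Yj} = \theta_D \hat\beta_{Xj} + \theta_M \hat\beta_{Mj} +
\varepsilon_j$, where $\theta_D$ is the direct effect and $\theta_M$ the
mediator's effect on the outcome. The mediated effect is the difference
$\theta_T - \theta_D$ between the univariable (total) and multivariable
(direct) exposure coefficients, computed on the *same* SNP set so the
decomposition is internally consistent.

### Estimator variants and defaults

* **IVW weighting** — `weight_mode = "multiplicative_random"` by default: the
  fixed-effect SE is inflated by $\max(1, \sqrt{Q/(n-1)})$. Instrument
  heterogeneity is the rule in practice, and the floor at 1 means the two
  flavours agree on homogeneous data; `"fixed"` is available by flag.
* **Penalization** — weights are multiplied by $\min(1, 20\,p_j)$, where
  $p_j$ is the upper $\chi^2_1$ tail of SNP $j$'s contribution to Cochran's
  $Q$ at the initial estimate. The constant 20 follows the convention of the
  penalized estimator family and is configurable.
* **Robust fits** — Tukey biweight, tuning constant 4.685, iteratively
  reweighted least squares on residuals standardized by the reported
  precisions, convergence 1e-8. This matches the generic "robust IVW/Egger"
  labels without committing to a specific software stack.
* **MR-Egger** — SNPs are re-oriented so every exposure beta is positive
  before fitting (the intercept is otherwise uninterpretable); the intercept
  estimates average directional pleiotropy.
* **Medians** — the weighted median is the 50th weighted percentile of the
  per-SNP Wald ratios with weights $\propto 1/se(\text{ratio})^2$, linear
  interpolation across the cumulative weight function. SEs are parametric
  bootstrap (default 1000 draws, seeded): betas resampled at their reported
  SEs. The estimator is consistent when valid instruments carry more than
  half the weight; note this guarantee concerns *balanced* contamination —
  under strictly one-sided (directional) contamination at fixed reported SEs
  the weighted median converges to a shifted weighted percentile, a bias that
  does not vanish as the number of SNPs grows.
* **Radial outliers** — the radial formulation (regress
  $\hat\beta_{Yj}/se_j$ on $\hat\beta_{Xj}/se_j$ through the origin) shares
  its point estimate with fixed-effect IVW; SNPs whose $Q$ contribution
  exceeds the $\chi^2_1$ quantile at `alpha_level` (default 0.05) are removed,
  iterating until stable (single-pass by flag — published analyses do not
  always say which was used, so both are supported).
* **Two-sided p-values** are normal-reference throughout, matching the
  Wald-style confidence intervals the field reports.

### The horseshoe estimator (MR-horse)

`mr_horse()` treats the true instrument strengths $\beta_{xj}$ and per-SNP
direct effects $\alpha_j$ as unknowns:

$$\hat\beta_{Yj} \sim N(\theta \beta_{xj} + \alpha_j, se(\hat\beta_{Yj})^2),
\quad \hat\beta_{Xj} \sim N(\beta_{xj}, se(\hat\beta_{Xj})^2),$$

with a horseshoe prior on $\alpha_j$ (per-SNP half-Cauchy local scales
$\phi_j$, half-Cauchy(0,1) global scale $\tau$) and a per-SNP correlation
$\rho_j \sim 2\,\mathrm{Beta}(10,10)-1$ between $\alpha_j$ and $\beta_{xj}$,
so the model stays consistent when pleiotropy is correlated with instrument
strength (InSIDE violation) — the regime in which IVW and Egger are both
biased. Priors: $\theta \sim N(0,1)$. Sampling uses JAGS with 4 chains, 1000
adaptation + 1000 burn-in and 1000 retained iterations per chain, seeded per
chain. Convergence is gated on the split-chain $\hat R$ of $\theta$
(flagged and warned above 1.05); the causal estimate is the posterior mean,
the reported interval the 2.5–97.5% quantile range.

## Genetic scores

`compute_scores()` evaluates $GS_i = \sum_k \beta_k x_{ik}$ and standardizes
by the analysis sample's own mean and SD (the 1/n population form — for a
cohort of thousands the distinction from 1/(n−1) is immaterial, but the 1/n
form reproduces small worked examples exactly). Missing dosages are
mean-imputed as $2p_k$, preserving the expectation. `theoretical_sd_effect()`
returns $\sqrt{\sum_k 2 p_k (1-p_k) \beta_k^2}$ — the SD of the raw score
under Hardy–Weinberg equilibrium and between-SNP independence. Because each
weight is a per-allele *trait* effect, this SD is also the expected trait
shift in years per population SD of the score, the number cohort estimates
are compared against. Both the sample and the theoretical standardization are
reported.

## Carrier-cohort validation

**Phenotype derivation.** `derive_menopause_phenotype()` encodes the
questionnaire rules: a woman contributes a natural-menopause event only if
the reason her periods stopped is natural menopause alone *and* the derived
event age (age at last menstruation + 1 year, from the "no period in the past
year" item) precedes RRSO, any cancer diagnosis, death and interview;
premenopausal women (period in the past year; periods not stopped; stopping
due to medication/oral contraceptives under age 40, pregnancy or
breastfeeding) are censored at the earliest censoring cause; everyone still
premenopausal at 60 becomes an administrative event at 60; RRSO/hysterectomy
and other non-natural reasons censor at the age at last period; records with
the needed ages missing, or contradictory (last menstruation after
interview), are excluded with a logged reason. The medication clause at 40+
is not classifiable as premenopausal and not natural, so such records censor
at the age at last period; where the age needed for the 40+ decision is
missing the record is excluded — the questionnaire rules do not define these
cases, so the package takes the conservative reading.

**Ascertainment weights.** Clinic-recruited carrier series oversample
affected women. `compute_cohort_weights()` assigns, within each age stratum
(default bounds 18, 25, 30, …, 70, 80 years at the event/censoring age),
$w_{aff} = p_s N_s / n_{aff,s}$ and $w_{unaff} = (1-p_s) N_s /(N_s -
n_{aff,s})$, where $p_s$ is the cumulative incidence at the stratum's upper
bound from an age-specific incidence table. The weighted affected fraction
then equals $p_s$ identically. Strata that cannot support the formula (no
affected members with $p_s > 0$, or all affected with $p_s < 1$) merge into
their nearest younger neighbour with a warning. The precise weight formula in
the cited kin-cohort literature is not spelled out in the source analyses;
this stratum-matching form is the implementable reading of "weighted such
that observed incidence matches established rates".

**Censored regression.** `censreg()` maximizes the weighted censored-normal
(Tobit-type) log-likelihood — events contribute the normal density, censored
rows the upper-tail probability, each raised to its sampling weight — by BFGS
on (coefficients, log residual SD), starting from OLS on the uncensored rows,
with analytic gradients and a gradient-norm tolerance of 1e-8 (max 200
iterations). Variance is the cluster-level sandwich: per-observation scores
summed within family, with the $G/(G-1)$ small-sample factor. With no
censoring, unit weights and singleton clusters the fit reduces to OLS (this
is a test). Homoscedastic residuals are assumed — the canonical choice where
the source analyses say only "linear regression models allowing for a
censored outcome". AAM, which is fully observed, uses the same routine with
all statuses set to observed, i.e. plain weighted linear regression with
cluster-robust SEs. Birth-cohort adjustment uses the bins <1940, 1940–1949,
1950–1959, ≥1960 (reference = earliest).

## Synthetic data: what it emulates, and what it does not

`gen_twosample_sumstats()` draws, in fixed order (alleles, frequencies,
reported SEs, true effects, direct effects, mediator effects, sampling noise,
presentation flips): effect-allele frequencies uniform on (0.05, 0.95);
reported SEs log-uniform (exposure 0.005–0.015, outcome 0.01–0.03 — the
magnitudes of large reproductive-trait GWAS and carrier-consortium outcome
GWAS); true exposure effects as $5.45\,se_{Xj} + |N(0, 0.1)|$ years/allele,
so every instrument clears the genome-wide discovery threshold
($z = 5.45 \leftrightarrow p = 5\times10^{-8}$) exactly as published
instrument lists do — without the truncation, near-null instruments whose
estimated sign flips during Egger orientation systematically bias the
intercept, an artifact of an unrealistic instrument set rather than of the
estimator; direct effects $\alpha_j$ per the pleiotropy mode (balanced,
directional, or correlated with instrument strength via
$\alpha_j = \rho\,\mathrm{scale}(\beta_{Xj})\sigma_\alpha +$ residual, the
standard InSIDE-violation construction); and reported estimates drawn at the
reported SEs. A configurable fraction of rows is presented allele-swapped
(30%) or on the opposite strand (10%), and 10% of SNPs are A/T or C/G, to
exercise harmonization. Mediator traits get a direct SNP effect plus an
exposure-mediated path, so the generating total effect is
$\theta_D + \theta_M\,\gamma_{X\to M}$.

`gen_carrier_cohort()` emulates a clinic-ascertained family cohort: family
sizes 1 + Poisson(0.6); dosages binomial at the score model's frequencies;
latent ANM normal with mean 51 and SD 4 years (13 and 1.5 for AAM), a
configurable effect per population-SD of the score (default 1.5 years — the
regime of reported carrier-cohort estimates), and an optional shared family
effect (default 0, since the analysis model handles family dependence only
through robust variance); RRSO in 40% of women uniform on 35–55; disease
onset from a piecewise-constant carrier-level incidence table (rates
0.002–0.022/year from 18 to 80); interview uniform on 25–75; families with an
affected member oversampled 2:1 by default. The real recruiting mechanism is
not quantified in the source cohort descriptions, so the oversampling
multiplier is a stand-in, not a claim about any study.

Passing tests on these generators establishes internal statistical
correctness — estimator calibration, robustness properties, recovery of known
truth under the stated model. They do not establish robustness to what the
generators omit: linkage disequilibrium between instruments (instrument lists
are pruned to independence, so this is by design), imputation dosage
uncertainty, non-normal trait distributions, informative censoring beyond the
modelled competing events, or real questionnaire noise.

## Numerical choices and degenerate inputs

* Harmonization matches variants by ID only; chr/pos are opaque metadata.
  Surrogate variants arrive via a precomputed two-column map
  (`apply_surrogate_map()`); no LD is computed in-package.
* The palindromic ambiguity window defaults to ±0.08 around 0.5 (exclude
  eaf ∈ [0.42, 0.58]) — published analyses say only "close to 0.5", so the
  window is explicit and configurable; palindromic SNPs outside it align by
  frequency matching (eaf vs 1 − eaf).
* Weighted quantiles interpolate at cumulative probability
  $(S_j - w_j/2)/S_n$; the dominant-weight breakdown case is approached in
  the limit rather than hit exactly.
* `mvmr_fit()` refuses condition numbers above 1e8 (collinear mediators) and
  drops identically-zero mediator columns, reducing to the nested model.
* Zero exposure betas are excluded from Wald ratios with a message; an
  all-censored outcome, fewer than 2 events, or a rank-deficient design stop
  `censreg()` with explicit errors.
* Bootstrap and MCMC seeds are arguments with recorded defaults; the
  pipeline records package version, config hash and seed in its YAML report.
* Multiple-testing adjustment across methods is deliberately absent: the
  estimator grid is a sensitivity analysis, and unadjusted two-sided
  p-values are the field's reporting convention.

## Problem sizes in the test suite

The suite exercises the chain at 25–288 instruments, 200–500 replicate
simulations for calibration checks (CI coverage, Q size, median robustness,
mediation sign), cohorts of 800–2000 families, and a 4×10⁵-genotype
Hardy–Weinberg simulation as the oracle for the theoretical per-SD score
effect; these sizes give Monte-Carlo error comfortably inside the asserted
tolerances while keeping the default test run fast.

## Known limitations

* Per-SNP outcome associations are taken as given; estimating them from
  individual-level carrier data (retrospective-likelihood HRs) is out of
  scope, as are genotype QC, imputation, and GWAS discovery.
* Age-stratified analyses are driven by supplying one outcome table per age
  stratum; the package does not estimate stratum-specific per-SNP effects.
* The mediated-effect SE is a parametric bootstrap (the source analyses do
  not describe one); a delta-method value assuming independence of total and
  direct estimates is returned alongside as a cross-check.
* `mr_horse` with few SNPs (< 10) is fragile and warns; its convergence gate
  is necessary but not sufficient, as with all MCMC.
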