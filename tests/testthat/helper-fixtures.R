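# fixtures built in code, shared across test files

# minimal valid instrument set (already harmonized)
toy_set <- function(beta_x, beta_y, se_y, se_x = rep(0.01, length(beta_x)),
                    mediator = NULL, se_m = NULL) {
  n <- length(beta_x)
  out <- data.frame(variant_id = sprintf("rs%03d", seq_len(n)),
                    effect_allele = rep("A", n), other_allele = rep("G", n),
                    eaf = rep(0.3, n),
                    beta_x = beta_x, se_x = se_x, beta_y = beta_y, se_y = se_y)
  meds <- character(0)
  if (!is.null(mediator)) {
    out$beta_bmi <- mediator
    out$se_bmi <- se_m %||% rep(0.01, n)
    meds <- "bmi"
  }
  structure(out, class = c("instrument_set", "data.frame"),
            exclusions = data.frame(variant_id = character(0),
                                    reason = character(0)),
            mediators = meds, palindrome_eaf_window = 0.08)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random harmonized fixture for oracle-equivalence checks
random_set <- function(n, seed, mediator = FALSE) {
  set.seed(seed)
  toy_set(beta_x = rnorm(n, 0, 0.1),
          beta_y = rnorm(n, 0, 0.05),
          se_y = runif(n, 0.01, 0.05),
          se_x = runif(n, 0.005, 0.02),
          mediator = if (mediator) rnorm(n, 0, 0.05),
          se_m = if (mediator) runif(n, 0.005, 0.02))
}

# small score model with HWE-compatible frequencies
toy_score_model <- function(k = 20, seed = 1, label = "GS") {
  set.seed(seed)
  genetic_score_model(sprintf("s%03d", seq_len(k)),
                      sample(c("A", "C", "G", "T"), k, replace = TRUE),
                      weight = rnorm(k, 0, 0.1),
                      eaf = runif(k, 0.1, 0.9), label = label)
}

# one questionnaire record with overridable fields
q_record <- function(...) {
  rec <- list(had_period_past_year = FALSE, reason_stopped = NA_character_,
              age_last_menstruation = NA_real_, age_rrso = NA_real_,
              age_cancer_diagnosis = NA_real_, age_interview = 55,
              age_death = NA_real_)
  utils::modifyList(rec, list(...))
}
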