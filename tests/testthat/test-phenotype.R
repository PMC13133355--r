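test_that("natural menopause requires precedence over RRSO, diagnosis and interview", {
  # reason natural at 49 (last period 48), RRSO at 52, interview 55 -> event at 49
  rec <- q_record(reason_stopped = "natural menopause",
                  age_last_menstruation = 48, age_rrso = 52)
  out <- derive_menopause_phenotype(rec)
  expect_equal(out$time, 49)
  expect_equal(out$status, 1L)

  # same but RRSO before the menopause age -> censored at RRSO
  rec2 <- q_record(reason_stopped = "natural menopause",
                   age_last_menstruation = 48, age_rrso = 47)
  out2 <- derive_menopause_phenotype(rec2)
  expect_equal(out2$time, 47)
  expect_equal(out2$status, 0L)
})

test_that("event age adds one year to age at last menstruation", {
  rec <- q_record(reason_stopped = "natural menopause",
                  age_last_menstruation = 50)
  out <- derive_menopause_phenotype(rec)
  expect_equal(out$time, 51)
  expect_equal(out$status, 1L)
})

test_that("women still premenopausal at 60 get an administrative event at 60", {
  rec <- q_record(had_period_past_year = TRUE, age_interview = 63)
  out <- derive_menopause_phenotype(rec)
  expect_equal(out$time, 60)
  expect_equal(out$status, 1L)
  expect_equal(out$censor_reason, "admin_cap")
})

test_that("the full constructed rule table derives as specified", {
  cases <- list(
    # premenopausal: period in past year, censored at interview
    list(rec = q_record(had_period_past_year = TRUE, age_interview = 45),
         time = 45, status = 0L, included = TRUE),
    # periods not stopped -> premenopausal, censored at earliest censor (RRSO)
    list(rec = q_record(age_rrso = 44, age_interview = 50),
         time = 44, status = 0L, included = TRUE),
    # medication under 40 -> premenopausal
    list(rec = q_record(reason_stopped = "medication",
                        age_last_menstruation = 35, age_interview = 38),
         time = 38, status = 0L, included = TRUE),
    # medication at 40+ -> not premenopausal, censored at last period
    list(rec = q_record(reason_stopped = "medication",
                        age_last_menstruation = 45, age_interview = 50),
         time = 45, status = 0L, included = TRUE),
    # pregnancy -> premenopausal regardless of age
    list(rec = q_record(reason_stopped = "pregnancy",
                        age_last_menstruation = 41, age_interview = 43),
         time = 43, status = 0L, included = TRUE),
    # natural menopause before cancer diagnosis -> event
    list(rec = q_record(reason_stopped = "natural menopause",
                        age_last_menstruation = 47, age_cancer_diagnosis = 53),
         time = 48, status = 1L, included = TRUE),
    # natural menopause after cancer diagnosis -> censored at diagnosis
    list(rec = q_record(reason_stopped = "natural menopause",
                        age_last_menstruation = 47, age_cancer_diagnosis = 42),
         time = 42, status = 0L, included = TRUE),
    # natural menopause reported at/after the cap -> administrative event at 60
    list(rec = q_record(reason_stopped = "natural menopause",
                        age_last_menstruation = 61, age_interview = 65),
         time = 60, status = 1L, included = TRUE),
    # RRSO as the reason -> premenopausal until last period (censored there)
    list(rec = q_record(reason_stopped = "rrso", age_last_menstruation = 43,
                        age_rrso = 43, age_interview = 50),
         time = 43, status = 0L, included = TRUE),
    # hysterectomy -> censored at last period
    list(rec = q_record(reason_stopped = "hysterectomy",
                        age_last_menstruation = 46),
         time = 46, status = 0L, included = TRUE),
    # chemotherapy / unspecified reasons never count as natural menopause
    list(rec = q_record(reason_stopped = "chemotherapy",
                        age_last_menstruation = 39, age_cancer_diagnosis = 39),
         time = 39, status = 0L, included = TRUE),
    list(rec = q_record(reason_stopped = "unspecified",
                        age_last_menstruation = 48),
         time = 48, status = 0L, included = TRUE),
    # stopped with missing ages -> excluded
    list(rec = q_record(reason_stopped = "natural menopause"),
         included = FALSE, why = "missing_age_at_menopause"),
    list(rec = q_record(reason_stopped = "medication"),
         included = FALSE, why = "missing_age_at_menopause"),
    # contradictory ages -> excluded
    list(rec = q_record(reason_stopped = "natural menopause",
                        age_last_menstruation = 58, age_interview = 50),
         included = FALSE, why = "contradictory_ages"),
    # death before interview caps the censoring bound
    list(rec = q_record(had_period_past_year = TRUE, age_death = 41,
                        age_interview = 41),
         time = 41, status = 0L, included = TRUE))

  tab <- do.call(rbind, lapply(cases, function(cs) as.data.frame(cs$rec)))
  out <- derive_menopause_phenotype(tab)
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    expect_equal(out$included[i], cs$included, label = paste("case", i, "included"))
    if (cs$included) {
      expect_equal(out$time[i], cs$time, label = paste("case", i, "time"))
      expect_equal(out$status[i], cs$status, label = paste("case", i, "status"))
    } else {
      expect_equal(out$exclude_reason[i], cs$why, label = paste("case", i, "reason"))
    }
  }
})
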