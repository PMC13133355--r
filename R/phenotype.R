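#' Derive censored age-at-natural-menopause observations from questionnaire data
#'
#' Applies the questionnaire decision rules used for family-based carrier
#' cohorts. Per woman, the censoring bound is the earliest of age at
#' risk-reducing salpingo-oophorectomy (RRSO), any cancer diagnosis, death,
#' interview, and the administrative cap (`admin_cap`, default 60, at which
#' every woman is considered menopausal). The rules, in order:
#'
#' 1. Premenopausal (censored at the bound; an *event* at `admin_cap` when the
#'    bound is the cap itself): period in the past year; periods not stopped;
#'    reason for stopping is medication / oral-contraceptive use while younger
#'    than 40, pregnancy, or breastfeeding.
#' 2. Natural menopause event: reason is natural menopause *alone*, at age
#'    `age_last_menstruation + 1` (the "no period in the past year" rule), and
#'    only if that age precedes RRSO, any cancer diagnosis, death and
#'    interview; otherwise censored at the bound.
#' 3. Reason RRSO / hysterectomy (and other non-natural reasons:
#'    chemotherapy, radiotherapy, unspecified; medication at 40+): considered
#'    premenopausal until the age at last period, i.e. censored there.
#' 4. Periods stopped but age at last menstruation missing, or contradictory
#'    ages (last menstruation after interview): record excluded with a reason.
#'
#' @param data data frame with columns `had_period_past_year` (logical),
#'   `reason_stopped` (character; `NA` = periods have not stopped; recognised
#'   values: `"natural menopause"`, `"medication"`, `"oral contraceptive"`,
#'   `"pregnancy"`, `"breastfeeding"`, `"rrso"`, `"hysterectomy"`,
#'   `"chemotherapy"`, `"radiotherapy"`, `"unspecified"`),
#'   `age_last_menstruation`, `age_rrso`, `age_cancer_diagnosis`,
#'   `age_interview`, `age_death` (ages in years, `NA` when not applicable).
#' @param admin_cap administrative menopause age (years, default 60).
#' @return data frame (class `censored_obs`) with one row per input row:
#'   `time` (years), `status` (`1` natural/administrative menopause event,
#'   `0` right-censored), `censor_reason`, `included` (logical),
#'   `exclude_reason`.
#' @export
derive_menopause_phenotype <- function(data, admin_cap = 60) {
  data <- as.data.frame(data)
  need <- c("had_period_past_year", "reason_stopped", "age_last_menstruation",
            "age_rrso", "age_cancer_diagnosis", "age_interview", "age_death")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop_("missing column(s): ", paste(miss, collapse = ", "))
  n <- nrow(data)

  pmin_na <- function(...) {
    m <- do.call(pmin, c(lapply(list(...), function(x) ifelse(is.na(x), Inf, x))))
    m
  }
  bound <- pmin_na(data$age_rrso, data$age_cancer_diagnosis, data$age_death,
                   data$age_interview, rep(admin_cap, n))
  bound_is_cap <- bound >= admin_cap
  bound <- pmin(bound, admin_cap)

  time <- rep(NA_real_, n)
  status <- rep(NA_integer_, n)
  creason <- rep(NA_character_, n)
  included <- rep(TRUE, n)
  why <- rep(NA_character_, n)

  reason <- tolower(ifelse(is.na(data$reason_stopped), "", data$reason_stopped))
  stopped <- reason != ""
  age_lm <- data$age_last_menstruation

  premeno_reason <- reason %in% c("pregnancy", "breastfeeding") |
    (reason %in% c("medication", "oral contraceptive") &
       !is.na(age_lm) & age_lm < 40)
  med_missing_age <- reason %in% c("medication", "oral contraceptive") & is.na(age_lm)
  premeno <- (data$had_period_past_year %in% TRUE) | !stopped | premeno_reason

  natural <- reason == "natural menopause" & !premeno
  other_stop <- stopped & !premeno & !natural & !med_missing_age

  # exclusions first: periods stopped without a usable age, contradictions
  excl <- (stopped & !premeno & is.na(age_lm)) | med_missing_age
  why[excl] <- "missing_age_at_menopause"
  contradict <- !is.na(age_lm) & !is.na(data$age_interview) &
    age_lm > data$age_interview
  excl2 <- contradict & !excl
  why[excl2] <- "contradictory_ages"
  included[excl | excl2] <- FALSE

  # premenopausal women: censored at the bound; event when the bound is the cap
  idx <- premeno & included
  time[idx] <- bound[idx]
  status[idx] <- ifelse(bound_is_cap[idx], 1L, 0L)
  creason[idx] <- ifelse(bound_is_cap[idx], "admin_cap", "premenopausal_at_bound")

  # natural menopause: event at age at last menstruation + 1 if it precedes
  # every censoring cause; administrative event when it reaches the cap first
  idx <- natural & included
  ev_age <- age_lm + 1
  event <- idx & ev_age < bound & ev_age < admin_cap
  time[event] <- ev_age[event]
  status[event] <- 1L
  creason[event] <- "natural_menopause"
  capped <- idx & !event & bound_is_cap
  time[capped] <- admin_cap
  status[capped] <- 1L
  creason[capped] <- "admin_cap"
  late <- idx & !event & !bound_is_cap
  time[late] <- bound[late]
  status[late] <- 0L
  creason[late] <- "event_after_censoring"

  # surgical / other non-natural reasons: premenopausal until age at last period
  idx <- other_stop & included
  t0 <- pmin(age_lm[idx], bound[idx])
  time[idx] <- t0
  status[idx] <- ifelse(t0 >= admin_cap, 1L, 0L)
  creason[idx] <- ifelse(t0 >= admin_cap, "admin_cap", "nonnatural_stop")

  structure(data.frame(time = time, status = status, censor_reason = creason,
                       included = included, exclude_reason = why,
                       stringsAsFactors = FALSE),
            class = c("censored_obs", "data.frame"), admin_cap = admin_cap)
}
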