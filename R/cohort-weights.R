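#' Age-specific incidence table
#'
#' Contiguous, non-overlapping age intervals with annual disease incidence
#' rates (per carrier gene if desired — supply one table per gene).
#'
#' @param age_lo,age_hi interval bounds in years (`[age_lo, age_hi)`),
#'   contiguous and increasing.
#' @param rate annual incidence rates (non-negative).
#' @return an `incidence_table` data frame.
#' @export
incidence_table <- function(age_lo, age_hi, rate) {
  stopifnot(length(age_lo) == length(age_hi), length(rate) == length(age_lo))
  if (any(rate < 0)) stop_("incidence rates must be non-negative")
  o <- order(age_lo)
  age_lo <- age_lo[o]; age_hi <- age_hi[o]; rate <- rate[o]
  if (any(age_hi <= age_lo)) stop_("intervals must have age_hi > age_lo")
  if (length(age_lo) > 1 && any(abs(age_lo[-1] - age_hi[-length(age_hi)]) > 1e-9))
    stop_("intervals must be contiguous and non-overlapping")
  structure(data.frame(age_lo = age_lo, age_hi = age_hi, rate = rate),
            class = c("incidence_table", "data.frame"))
}

#' Cumulative hazard and cumulative incidence at given ages
#' @noRd
cum_hazard <- function(inc, age) {
  vapply(age, function(a) {
    yrs <- pmax(0, pmin(a, inc$age_hi) - inc$age_lo)
    sum(yrs * inc$rate)
  }, numeric(1))
}

cum_incidence <- function(inc, age) 1 - exp(-cum_hazard(inc, age))

#' Weighted-cohort sampling weights for an ascertained carrier series
#'
#' Carrier cohorts recruited through genetic-testing clinics oversample
#' affected (and young affected) individuals. The weighted-cohort correction
#' assigns sampling weights so that, within each age stratum, the weighted
#' fraction of affected individuals equals the fraction implied by established
#' age-specific incidence rates. With `N_s` individuals in stratum `s` of whom
#' `n_aff` are affected and implied affected probability `p_s` (cumulative
#' incidence at the stratum's upper age bound):
#' `w_aff = p_s * N_s / n_aff`, `w_unaff = (1 - p_s) * N_s / (N_s - n_aff)`,
#' making the weighted affected fraction exactly `p_s`.
#'
#' Strata with zero affected individuals but `p_s > 0` (or all affected with
#' `p_s < 1`) are merged with the nearest younger stratum, with a warning.
#'
#' @param age age at event/censoring per individual (years).
#' @param affected logical (or 0/1) disease status per individual.
#' @param incidence an [incidence_table()].
#' @param age_breaks stratum boundaries in years (default
#'   `c(18, 25, 30, ..., 70, 80)`); individuals are assigned by `age`.
#' @return a `cohort_weights` object: data frame with per-individual `weight`
#'   and `stratum`; attribute `strata` holds per-stratum diagnostics
#'   (`n`, `n_affected`, `p_implied`, `observed_fraction`, `weighted_fraction`).
#' @export
compute_cohort_weights <- function(age, affected,
                                   incidence,
                                   age_breaks = c(18, seq(25, 70, by = 5), 80)) {
  stopifnot(length(age) == length(affected))
  affected <- as.logical(affected)
  if (anyNA(age) || anyNA(affected)) stop_("age/affected must be complete")
  br <- sort(unique(age_breaks))
  if (max(age) >= max(br)) br[length(br)] <- max(age) + 1e-9
  br[1] <- min(br[1], min(age))
  stratum <- cut(age, breaks = br, right = FALSE, include.lowest = TRUE)
  lev <- levels(stratum)
  upper <- br[-1]

  # merge degenerate strata downward until every stratum has both statuses
  # represented wherever 0 < p_s < 1
  grp <- as.integer(stratum)
  repeat {
    tab_n <- tapply(rep(1, length(grp)), grp, sum)
    tab_a <- tapply(affected, grp, sum)
    gids <- as.integer(names(tab_n))
    p_s <- cum_incidence(incidence, upper[gids])
    bad <- gids[(tab_a == 0 & p_s > 0) | (tab_a == tab_n & p_s < 1)]
    if (!length(bad)) break
    g <- bad[1]
    lower_gids <- gids[gids < g]
    target <- if (length(lower_gids)) max(lower_gids) else min(gids[gids > g])
    if (!is.finite(target) || target == g) stop_("cannot merge degenerate stratum")
    warning("merging age stratum ", lev[g], " into neighbour (degenerate counts)",
            call. = FALSE)
    grp[grp == g] <- target
    # merged group keeps the larger upper bound for its implied probability
    upper[target] <- max(upper[target], upper[g])
  }

  w <- numeric(length(age))
  gids <- sort(unique(grp))
  diag_rows <- vector("list", length(gids))
  for (i in seq_along(gids)) {
    g <- gids[i]
    in_g <- grp == g
    N <- sum(in_g); na <- sum(affected[in_g])
    p <- cum_incidence(incidence, upper[g])
    w_aff <- if (na > 0) p * N / na else 0
    w_un <- if (na < N) (1 - p) * N / (N - na) else 0
    w[in_g] <- ifelse(affected[in_g], w_aff, w_un)
    wf <- sum(w[in_g] * affected[in_g]) / sum(w[in_g])
    diag_rows[[i]] <- data.frame(stratum = g, upper_age = upper[g], n = N,
                                 n_affected = na, p_implied = p,
                                 observed_fraction = na / N,
                                 weighted_fraction = wf)
  }
  if (any(!is.finite(w) | w <= 0))
    stop_("non-positive or non-finite weight produced; check incidence table")
  structure(data.frame(weight = w, stratum = grp),
            class = c("cohort_weights", "data.frame"),
            strata = do.call(rbind, diag_rows))
}
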