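#' Harmonize exposure, outcome and mediator summary statistics
#'
#' Builds the analysis-ready instrument set: intersects variant IDs, aligns
#' every table to the exposure's effect allele (sign-flipping betas and
#' complementing frequencies where the allele pair is swapped, resolving
#' opposite-strand reports by base complement), and excludes strand-ambiguous
#' (A/T, C/G) variants whose effect-allele frequency is within
#' `palindrome_eaf_window` of 0.5 in any table. Palindromic variants outside
#' the window are aligned by frequency matching (eaf vs 1-eaf). Every dropped
#' variant is logged with a reason; the exclusion log partitions the shared
#' variants into retained and excluded.
#'
#' @param exposure,outcome `assoc_table`s (see [read_sumstats()]).
#' @param mediators optional named list of `assoc_table`s (e.g.
#'   `list(bmi = ...)`); their aligned betas/ses join the set as
#'   `beta_<name>` / `se_<name>` columns.
#' @param palindrome_eaf_window half-width of the ambiguity window around 0.5
#'   (default 0.08: eaf in \[0.42, 0.58\] is ambiguous).
#' @param orient_exposure if `TRUE`, rows are re-oriented so the
#'   exposure-increasing allele is the effect allele.
#' @return an `instrument_set`: data frame with columns `variant_id`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta_x`, `se_x`, `beta_y`,
#'   `se_y` (+ mediator columns), with attributes `exclusions` (data frame
#'   `variant_id`, `reason`) and `mediators` (character).
#' @export
harmonize <- function(exposure, outcome, mediators = NULL,
                      palindrome_eaf_window = 0.08,
                      orient_exposure = FALSE) {
  tables <- c(list(outcome = outcome), mediators)
  if (!is.null(mediators) &&
      (is.null(names(mediators)) || any(names(mediators) == "")))
    stop_("mediators must be a named list")

  ids <- exposure$variant_id
  for (t in tables) ids <- intersect(ids, t$variant_id)
  excl <- data.frame(variant_id = character(0), reason = character(0),
                     stringsAsFactors = FALSE)

  ex <- exposure[match(ids, exposure$variant_id), , drop = FALSE]
  set <- data.frame(variant_id = ids,
                    effect_allele = ex$effect_allele,
                    other_allele = ex$other_allele,
                    eaf = ex$eaf, beta_x = ex$beta, se_x = ex$se,
                    stringsAsFactors = FALSE)
  pal <- is_palindromic(set$effect_allele, set$other_allele)
  drop <- rep(FALSE, length(ids))
  reason <- rep(NA_character_, length(ids))
  mark <- function(cond, why) {
    newly <- cond & !drop
    drop[newly] <<- TRUE
    reason[newly] <<- why
  }
  ambiguous <- function(f) abs(f - 0.5) < palindrome_eaf_window
  mark(pal & ambiguous(set$eaf), "palindromic_ambiguous")

  for (nm in names(tables)) {
    t <- tables[[nm]]
    t <- t[match(ids, t$variant_id), , drop = FALSE]
    beta <- t$beta; se <- t$se
    direct <- t$effect_allele == set$effect_allele & t$other_allele == set$other_allele
    swap <- t$effect_allele == set$other_allele & t$other_allele == set$effect_allele
    sdirect <- comp_allele(t$effect_allele) == set$effect_allele &
      comp_allele(t$other_allele) == set$other_allele
    sswap <- comp_allele(t$effect_allele) == set$other_allele &
      comp_allele(t$other_allele) == set$effect_allele

    flip <- rep(NA, length(ids)) # TRUE: negate beta; NA: unresolvable
    # palindromic pairs: direct/swap/strand tests are degenerate; use frequency
    flip[pal] <- ifelse(
      (direct | swap | sdirect | sswap)[pal],
      abs(t$eaf[pal] - set$eaf[pal]) > abs((1 - t$eaf[pal]) - set$eaf[pal]),
      NA)
    flip[!pal & (direct | sdirect)] <- FALSE
    flip[!pal & (swap | sswap) & !(direct | sdirect)] <- TRUE
    mark(pal & !is.na(flip) & ambiguous(t$eaf), "palindromic_ambiguous")
    mark(is.na(flip), "allele_mismatch")

    beta[flip %in% TRUE] <- -beta[flip %in% TRUE]
    prefix <- if (nm == "outcome") c("beta_y", "se_y") else paste0(c("beta_", "se_"), nm)
    set[[prefix[1]]] <- beta
    set[[prefix[2]]] <- se
  }

  if (any(drop)) {
    excl <- rbind(excl, data.frame(variant_id = ids[drop], reason = reason[drop],
                                   stringsAsFactors = FALSE))
    set <- set[!drop, , drop = FALSE]
  }
  rownames(set) <- NULL

  if (orient_exposure) {
    neg <- set$beta_x < 0
    set$beta_x[neg] <- -set$beta_x[neg]
    set$eaf[neg] <- 1 - set$eaf[neg]
    tmp <- set$effect_allele[neg]
    set$effect_allele[neg] <- set$other_allele[neg]
    set$other_allele[neg] <- tmp
    for (col in setdiff(grep("^beta_", names(set), value = TRUE), "beta_x"))
      set[[col]][neg] <- -set[[col]][neg]
  }

  structure(set,
            class = c("instrument_set", "data.frame"),
            exclusions = excl,
            mediators = if (is.null(mediators)) character(0) else names(mediators),
            palindrome_eaf_window = palindrome_eaf_window)
}

#' Exclusion log of an instrument set
#' @param set an `instrument_set`.
#' @return data frame with columns `variant_id`, `reason`.
#' @export
exclusions <- function(set) attr(set, "exclusions")

#' Mediator labels carried by an instrument set
#' @param set an `instrument_set`.
#' @return character vector of mediator names (possibly empty).
#' @export
mediator_names <- function(set) attr(set, "mediators")

#' Keep a subset of rows of an instrument set, preserving attributes
#' @noRd
set_subset <- function(set, keep) {
  out <- set[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("exclusions", "mediators", "palindrome_eaf_window")] <-
    attributes(set)[c("exclusions", "mediators", "palindrome_eaf_window")]
  class(out) <- class(set)
  out
}

#' Partition an instrument set by SNP annotation
#'
#' Splits the retained SNPs into disjoint subsets by a categorical label (e.g.
#' DNA-damage-response vs non-DDR instruments for age at natural menopause).
#' SNPs absent from the annotation get label `"unannotated"`.
#'
#' @param set an `instrument_set`.
#' @param annotation data frame with columns `variant_id`, `label`; at most one
#'   label per variant (conflicting duplicates are an error).
#' @return named list of `instrument_set`s whose union is `set`.
#' @export
subset_by_annotation <- function(set, annotation = NULL) {
  if (is.null(annotation) || nrow(annotation) == 0) {
    return(stats::setNames(list(set), "unannotated"))
  }
  stopifnot(all(c("variant_id", "label") %in% names(annotation)))
  ann <- unique(annotation[c("variant_id", "label")])
  if (anyDuplicated(ann$variant_id))
    stop_("conflicting annotation labels for variant(s): ",
          paste(unique(ann$variant_id[duplicated(ann$variant_id)]), collapse = ", "))
  lab <- ann$label[match(set$variant_id, ann$variant_id)]
  lab[is.na(lab)] <- "unannotated"
  lapply(split(seq_len(nrow(set)), lab), function(i) set_subset(set, i))
}
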