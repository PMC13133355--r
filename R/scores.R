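#' Define a genetic score model
#'
#' A genetic score (GS) is the weighted allele count
#' `GS = sum_k beta_k * x_k`, where `beta_k` is the per-allele trait effect of
#' SNP `k` and `x_k` the dosage of its effect allele. The model stores weights
#' and published effect-allele frequencies, which determine the theoretical
#' population SD of the raw score under Hardy-Weinberg equilibrium.
#'
#' @param variant_id character vector of unique SNP identifiers.
#' @param effect_allele effect alleles (A/C/G/T).
#' @param weight per-allele weights, trait units (e.g. years) per allele.
#' @param eaf effect-allele frequencies, strictly in (0, 1); may contain `NA`
#'   if [theoretical_sd_effect()] is not needed.
#' @param label score label, e.g. `"ANM-GS"`, `"AAM-GS"`, `"AAMBMI-GS"`.
#' @return a `score_model` (data frame with a `label` attribute).
#' @export
genetic_score_model <- function(variant_id, effect_allele, weight, eaf = NA,
                                label = "GS") {
  n <- length(variant_id)
  stopifnot(length(effect_allele) == n, length(weight) == n)
  eaf <- rep_len(eaf, n)
  if (anyDuplicated(variant_id)) stop_("duplicate variant IDs in score model")
  if (any(!is.finite(weight))) stop_("non-finite weight(s)")
  if (any(!is.na(eaf) & (eaf <= 0 | eaf >= 1))) stop_("eaf must lie in (0, 1)")
  structure(data.frame(variant_id = variant_id,
                       effect_allele = toupper(effect_allele),
                       weight = weight, eaf = eaf, stringsAsFactors = FALSE),
            class = c("score_model", "data.frame"), label = label)
}

#' Compute standardized genetic scores from dosages
#'
#' Raw score per individual is `sum_k beta_k x_k`; standardized scores are
#' centred and scaled by the analysis sample's own mean and SD (the usual
#' within-cohort standardization). Missing dosages are mean-imputed as
#' `2 * eaf` (flagged); individuals with imputed dosages are counted in the
#' `"n_imputed"` attribute.
#'
#' @param model a [genetic_score_model()].
#' @param dosages numeric matrix or data frame, individuals x SNPs, entries in
#'   \[0, 2\], with column names covering `model$variant_id`.
#' @return data frame with columns `raw` and `standardized`; attributes
#'   `sample_mean`, `sample_sd`, `n_imputed`.
#' @export
compute_scores <- function(model, dosages) {
  stopifnot(inherits(model, "score_model"))
  dosages <- as.matrix(dosages)
  missing_snps <- setdiff(model$variant_id, colnames(dosages))
  if (length(missing_snps))
    stop_("dosage matrix lacks SNP(s): ", paste(missing_snps, collapse = ", "))
  d <- dosages[, model$variant_id, drop = FALSE]
  if (any(d < 0 | d > 2, na.rm = TRUE)) stop_("dosages must lie in [0, 2]")
  n_imputed <- 0L
  if (anyNA(d)) {
    if (anyNA(model$eaf[colSums(is.na(d)) > 0]))
      stop_("missing dosages require eaf for mean imputation")
    n_imputed <- sum(apply(is.na(d), 1, any))
    for (k in which(colSums(is.na(d)) > 0)) {
      d[is.na(d[, k]), k] <- 2 * model$eaf[k]
    }
  }
  raw <- drop(d %*% model$weight)
  m <- mean(raw)
  s <- sqrt(mean((raw - m)^2)) # population (1/n) SD of the analysis sample
  if (!is.finite(s) || s == 0) stop_("raw scores have zero variance; cannot standardize")
  structure(data.frame(raw = raw, standardized = (raw - m) / s),
            sample_mean = m, sample_sd = s, n_imputed = n_imputed)
}

#' Reweight a menarche score by BMI effect sizes
#'
#' Builds the BMI-weighted companion score: the same SNPs as the input model,
#' with weights replaced by their (harmonized) per-allele BMI effects. BMI
#' betas reported for the swapped allele are sign-flipped. SNPs without BMI
#' coverage are dropped with a message; more than 50% dropped is an error.
#'
#' @param aam_model a [genetic_score_model()] (apply any surrogate map to
#'   `bmi_assoc` beforehand).
#' @param bmi_assoc an `assoc_table` of per-allele BMI associations.
#' @return a `score_model` labelled `"AAMBMI-GS"`.
#' @export
build_bmi_weighted_score <- function(aam_model, bmi_assoc) {
  stopifnot(inherits(aam_model, "score_model"))
  idx <- match(aam_model$variant_id, bmi_assoc$variant_id)
  covered <- !is.na(idx)
  if (mean(covered) < 0.5)
    stop_(sum(!covered), " of ", nrow(aam_model),
          " SNPs lack BMI coverage (>50%); refusing to build score")
  if (any(!covered))
    message(sum(!covered), " SNP(s) without BMI coverage dropped")
  m <- aam_model[covered, , drop = FALSE]
  b <- bmi_assoc[idx[covered], , drop = FALSE]
  same <- b$effect_allele == m$effect_allele
  swapped <- b$other_allele == m$effect_allele & !same
  bad <- !(same | swapped)
  if (any(bad)) {
    message(sum(bad), " SNP(s) dropped for allele mismatch with BMI table")
    m <- m[!bad, , drop = FALSE]; b <- b[!bad, , drop = FALSE]
    same <- same[!bad]
  }
  w <- ifelse(same, b$beta, -b$beta)
  genetic_score_model(m$variant_id, m$effect_allele, w, m$eaf, label = "AAMBMI-GS")
}

#' Theoretical per-SD trait effect of a genetic score
#'
#' Under Hardy-Weinberg equilibrium and independence between SNPs, the raw
#' score `sum_k beta_k x_k` has population SD
#' `sqrt(sum_k 2 p_k (1 - p_k) beta_k^2)`. Because each weight is the
#' per-allele trait effect, this SD equals the expected trait shift (in trait
#' units, e.g. years) per 1-SD difference in the score — the "theoretical
#' effect size in the general population" against which cohort estimates are
#' compared.
#'
#' @param model a [genetic_score_model()] with frequencies for every SNP.
#' @return the per-SD trait effect (scalar, trait units).
#' @export
theoretical_sd_effect <- function(model) {
  stopifnot(inherits(model, "score_model"))
  if (anyNA(model$eaf))
    stop_("missing allele frequency for SNP(s): ",
          paste(model$variant_id[is.na(model$eaf)], collapse = ", "))
  sqrt(sum(2 * model$eaf * (1 - model$eaf) * model$weight^2))
}
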