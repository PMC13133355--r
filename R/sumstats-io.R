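#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated association table (GWAS-SSF-like dialect) with
#' required columns `variant_id`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`. Optional `chr`/`pos` columns are carried as opaque metadata.
#' Rows with missing `beta` or `se`, non-positive `se`, out-of-range `eaf`, or
#' alleles outside A/C/G/T are dropped and counted; the count is attached as
#' the `"n_dropped"` attribute and reported via a message.
#'
#' @param path path to a tab-separated file with a header line.
#' @return an `assoc_table` (data frame) of validated rows.
#' @export
read_sumstats <- function(path) {
  if (!file.exists(path)) stop_("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = NA)
  required <- c("variant_id", "effect_allele", "other_allele", "eaf", "beta", "se")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop_("missing required column(s): ", paste(missing_cols, collapse = ", "))
  for (col in c("eaf", "beta", "se")) {
    if (!is.numeric(tab[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[col]]))) & !is.na(tab[[col]]))
      stop_("non-numeric ", col, " at line ", bad[1] + 1L, " of ", path)
    }
  }
  as_assoc_table(tab, source = path)
}

#' Validate a data frame as an association table
#'
#' @param tab data frame with the columns documented in [read_sumstats()].
#' @param source label used in messages.
#' @return an `assoc_table` with invalid rows dropped (count in attribute
#'   `"n_dropped"`).
#' @export
as_assoc_table <- function(tab, source = "table") {
  required <- c("variant_id", "effect_allele", "other_allele", "eaf", "beta", "se")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop_("missing required column(s): ", paste(missing_cols, collapse = ", "))
  tab$effect_allele <- toupper(tab$effect_allele)
  tab$other_allele <- toupper(tab$other_allele)
  ok <- !is.na(tab$beta) & !is.na(tab$se) & tab$se > 0 &
    !is.na(tab$eaf) & tab$eaf > 0 & tab$eaf < 1 &
    tab$effect_allele %in% c("A", "C", "G", "T") &
    tab$other_allele %in% c("A", "C", "G", "T") &
    tab$effect_allele != tab$other_allele
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(n_dropped, " row(s) dropped from ", source,
            " (missing/invalid beta, se, eaf or alleles)")
  tab <- tab[ok, , drop = FALSE]
  if (anyDuplicated(tab$variant_id))
    stop_("duplicate variant IDs in ", source)
  rownames(tab) <- NULL
  structure(tab, class = c("assoc_table", "data.frame"), n_dropped = n_dropped)
}

#' Write a summary-statistics table
#'
#' Tab-separated, header line, no quoting: the dialect [read_sumstats()] reads.
#'
#' @param tab an `assoc_table` or compatible data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply a surrogate-variant replacement map
#'
#' Replaces variant IDs using a precomputed surrogate map (e.g. LD proxies
#' selected upstream so mediator effect sizes can be looked up); no LD is
#' computed here. Applied before harmonization.
#'
#' @param tab an `assoc_table`.
#' @param map data frame with columns `variant_id`, `surrogate_id`.
#' @return the table with mapped IDs.
#' @export
apply_surrogate_map <- function(tab, map) {
  stopifnot(all(c("variant_id", "surrogate_id") %in% names(map)))
  idx <- match(tab$variant_id, map$variant_id)
  hit <- !is.na(idx)
  tab$variant_id[hit] <- map$surrogate_id[idx[hit]]
  if (anyDuplicated(tab$variant_id)) stop_("surrogate map produces duplicate variant IDs")
  tab
}
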