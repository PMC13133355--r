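#' Run a configured end-to-end MR analysis
#'
#' Orchestrates simulate/load -> harmonize -> MR -> (optional) outlier removal
#' and multivariable mediation from a single configuration, and emits a
#' report bundle: a method-by-estimate table (one row per estimator, with
#' exponentiated scale, 95% CI and p, Egger intercepts in adjacent columns),
#' heterogeneity statistics, the harmonization exclusion log, the mediation
#' decomposition when mediators are present, and a machine-readable YAML of
#' every number. Runs are deterministic given the seed, which is recorded in
#' every artifact.
#'
#' @param config a list, or path to a YAML file, with fields:
#'   \describe{
#'     \item{simulation}{arguments for [sumstats_scenario()] (exactly one of
#'       `simulation` / `inputs` must be present).}
#'     \item{inputs}{list of file paths: `exposure`, `outcome`, optional named
#'       `mediators`, optional `annotation` (TSV `variant_id`, `label`).}
#'     \item{methods}{subset of `c("ivw", "egger", "median", "horse")`
#'       (default all but `horse`).}
#'     \item{penalized, robust}{logical; add penalized/robust estimator rows
#'       (default `TRUE`: the full sensitivity grid).}
#'     \item{outlier_removal}{logical; re-run IVW after radial outlier
#'       removal.}
#'     \item{mediation}{logical; run [mediation_decompose()] when mediators
#'       are available.}
#'     \item{palindrome_eaf_window}{passed to [harmonize()].}
#'     \item{seed}{integer (default 1).}
#'     \item{out_dir}{optional directory for TSV/YAML artifacts.}
#'   }
#' @return invisible list of class `mr_report`: `estimates` (data frame),
#'   `heterogeneity`, `exclusions`, `mediation` (or `NULL`), `outliers`,
#'   `set`, `config`, `seed`, `files` (paths written, if any).
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (!xor(!is.null(config$simulation), !is.null(config$inputs)))
    stop_("config must contain exactly one of 'simulation' or 'inputs'")
  seed <- as.integer(config$seed %||% 1L)
  methods <- config$methods %||% c("ivw", "egger", "median")
  penalized <- isTRUE(config$penalized %||% TRUE)
  robust <- isTRUE(config$robust %||% TRUE)

  stage <- "input"
  res <- tryCatch({
    if (!is.null(config$simulation)) {
      sim_args <- config$simulation
      sim_args$seed <- sim_args$seed %||% seed
      scen <- do.call(sumstats_scenario, sim_args)
      sim <- gen_twosample_sumstats(scen)
      exposure <- sim$exposure; outcome <- sim$outcome
      mediators <- if (!is.null(sim$mediator)) list(bmi = sim$mediator)
      truth <- sim$truth
      annotation <- NULL
    } else {
      inp <- config$inputs
      exposure <- read_sumstats(inp$exposure)
      outcome <- read_sumstats(inp$outcome)
      mediators <- if (!is.null(inp$mediators))
        lapply(inp$mediators, read_sumstats)
      annotation <- if (!is.null(inp$annotation))
        utils::read.delim(inp$annotation, stringsAsFactors = FALSE)
      truth <- NULL
    }

    stage <- "harmonize"
    set <- harmonize(exposure, outcome, mediators = mediators,
                     palindrome_eaf_window = config$palindrome_eaf_window %||% 0.08)

    stage <- "mr"
    rows <- list()
    add <- function(est) rows[[length(rows) + 1]] <<- mr_row(est)
    grid <- expand.grid(pen = c(FALSE, if (penalized) TRUE),
                        rob = c(FALSE, if (robust) TRUE))
    if ("median" %in% methods) {
      add(mr_median(set, "simple", seed = seed))
      add(mr_median(set, "weighted", seed = seed))
      add(mr_median(set, "penalized_weighted", seed = seed))
    }
    het <- NULL
    if ("ivw" %in% methods) {
      for (i in seq_len(nrow(grid))) {
        est <- mr_ivw(set, penalized = grid$pen[i], robust = grid$rob[i])
        if (!grid$pen[i] && !grid$rob[i]) het <- est$heterogeneity
        add(est)
      }
    }
    if ("egger" %in% methods) {
      for (i in seq_len(nrow(grid)))
        add(mr_egger(set, penalized = grid$pen[i], robust = grid$rob[i]))
    }
    if ("horse" %in% methods) add(mr_horse(set, seed = seed))

    outliers <- NULL
    if (isTRUE(config$outlier_removal)) {
      stage <- "outlier_removal"
      rad <- radial_outliers(set)
      outliers <- rad$outliers
      if (length(rad$outliers) && "ivw" %in% methods) {
        est <- mr_ivw(rad$set)
        est$method <- "IVW (outliers removed)"
        add(est)
      }
    }

    mediation <- NULL
    if (isTRUE(config$mediation %||% TRUE) && length(mediator_names(set))) {
      stage <- "mediation"
      mediation <- mediation_decompose(set, seed = seed)
      tot <- mr_row(mediation$total); tot$method <- "Total effect"
      dir <- mr_row(mediation$direct); dir$method <- "Direct effect"
      rows <- c(list(tot, dir), rows)
    }

    estimates <- do.call(rbind, rows)

    stage <- "report"
    files <- character(0)
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      f_est <- file.path(config$out_dir, "estimates.tsv")
      utils::write.table(estimates, f_est, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      f_excl <- file.path(config$out_dir, "exclusions.tsv")
      utils::write.table(exclusions(set), f_excl, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      cfg_stable <- config[setdiff(names(config), "out_dir")]
      machine <- list(
        package_version = as.character(utils::packageVersion("carriermr")),
        seed = seed,
        config_hash = sum(utf8ToInt(paste(deparse(cfg_stable), collapse = ""))),
        n_snps = nrow(set),
        estimates = lapply(seq_len(nrow(estimates)), function(i)
          as.list(estimates[i, ])),
        heterogeneity = if (!is.null(het))
          list(Q = het$Q, df = het$df, p = het$p_value, I2 = het$I2),
        outliers = as.list(outliers %||% character(0)),
        mediation = if (!is.null(mediation)) list(
          total = mediation$total$estimate, direct = mediation$direct$estimate,
          mediated = mediation$mediated, mediated_se = mediation$mediated_se))
      f_yaml <- file.path(config$out_dir, "report.yaml")
      yaml::write_yaml(machine, f_yaml, precision = 15)
      files <- c(estimates = f_est, exclusions = f_excl, yaml = f_yaml)
    }

    structure(list(estimates = estimates, heterogeneity = het,
                   exclusions = exclusions(set), mediation = mediation,
                   outliers = outliers, set = set, truth = truth,
                   config = config, seed = seed, files = files),
              class = "mr_report")
  }, error = function(e) {
    stop_("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })
  invisible(res)
}

#' @export
print.mr_report <- function(x, digits = 3, ...) {
  cat("MR analysis report (seed ", x$seed, ", ", nrow(x$set), " SNPs)\n", sep = "")
  tab <- x$estimates
  tab[] <- lapply(tab, function(col) if (is.numeric(col)) signif(col, digits) else col)
  print(tab, row.names = FALSE)
  if (!is.null(x$heterogeneity)) print(x$heterogeneity)
  invisible(x)
}
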