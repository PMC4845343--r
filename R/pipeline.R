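#' Pipeline configuration
#'
#' Exactly one of `input` (a cohort file readable by [read_cohort()]) or
#' `params` (generator parameters for [generate_cohort()]) must be given.
#'
#' @param input optional cohort file path.
#' @param params optional [cohort_params()].
#' @param alpha significance level.
#' @param assumption_grid fractions for the sensitivity analysis.
#' @param seed integer seed used for the generator and the imputation
#'   draws.
#' @param synonyms optional domain synonym map.
#' @param outdir optional output directory for [write_results()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, params = NULL, alpha = 0.05,
                            assumption_grid = c(0, 0.25, 0.5, 0.75, 1),
                            seed = 1L, synonyms = NULL, outdir = NULL) {
  if (is.null(input) == is.null(params))
    stop("exactly one of input or params must be specified")
  if (!is.null(params)) stopifnot(inherits(params, "cohort_params"))
  structure(list(input = input, params = params, alpha = alpha,
                 assumption_grid = assumption_grid, seed = as.integer(seed),
                 synonyms = synonyms, outdir = outdir),
            class = "pipeline_config")
}

.stage_log <- function(verbose, stage, n_in, n_out) {
  if (verbose)
    message(sprintf("[%s] %d records in, %d out", stage, n_in, n_out))
}

#' Run the full analysis pipeline
#'
#' Sequences every stage over one cohort: main-outcome selection census,
#' significance classification (main and any outcome), concordance summary
#' under both agreement definitions, risk-ratio table (model 1) for the
#' standard exposure set, interaction models (model 2) for the COI
#' exposures, Kaplan-Meier/log-rank time-to-publication analyses, and the
#' assumption-based sensitivity analysis. Identical config and seed yield
#' an identical bundle.
#'
#' @param config a [pipeline_config()].
#' @param verbose log stage record counts as messages.
#' @return list of class `pipeline_bundle`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- if (!is.null(config$input)) read_cohort(config$input)
  else generate_cohort(config$params, seed = config$seed)
  n <- length(cohort)
  alpha <- config$alpha
  published <- vapply(cohort, is_published, logical(1))
  .stage_log(verbose, "load", n, n)

  census <- selection_rule_census(cohort)

  main_cls <- vapply(cohort, abstract_main_significance, character(1),
                     alpha = alpha)
  any_cls <- vapply(cohort, function(p)
    classify_any_outcome(p$abstract, alpha), character(1))
  sig_census <- do.call(rbind, lapply(c("main", "any"), function(scope) {
    cls <- if (scope == "main") main_cls else any_cls
    data.frame(scope = scope,
               class = .SIG_LEVELS,
               count = vapply(.SIG_LEVELS, function(l) sum(cls == l),
                              integer(1)),
               row.names = NULL)
  }))
  .stage_log(verbose, "classify", n, n)

  concordance <- lapply(c("exact", "exact_or_lt10"), function(def)
    summarize_concordance(cohort, def, alpha = alpha,
                          synonyms = config$synonyms))
  names(concordance) <- c("exact", "exact_or_lt10")
  .stage_log(verbose, "concordance", sum(published),
             concordance$exact$n_comparable)

  exposures <- list(
    sig_reported = exposure_sig_reported(alpha),
    any_sig_reported = exposure_any_sig_reported(alpha),
    significant = exposure_significant(alpha),
    first_coi_any = exposure_coi("first", "any"),
    first_coi_financial_support = exposure_coi("first", "financial_support"),
    first_coi_received_gifts = exposure_coi("first", "received_gifts"),
    funding_none = exposure_funding_none())
  rr_table <- do.call(rbind, lapply(names(exposures), function(nm) {
    est <- tryCatch(crude_rr(build_table(cohort, exposures[[nm]])),
                    error = function(e) NULL)
    if (is.null(est))
      return(data.frame(exposure = nm, rr = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, n_used = NA_integer_))
    data.frame(exposure = nm, rr = est$rr, ci_low = est$ci_low,
               ci_high = est$ci_high, n_used = est$n_used)
  }))

  coi_exposures <- grep("^first_coi", names(exposures), value = TRUE)
  interaction_table <- do.call(rbind, lapply(coi_exposures, function(nm) {
    fit <- tryCatch(fit_interaction_model(cohort, exposures[[nm]],
                                          alpha = alpha),
                    error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(exposure = nm, rr_not_significant = NA_real_,
                        rr_significant = NA_real_,
                        rr_not_reported = NA_real_,
                        joint_statistic = NA_real_, joint_p = NA_real_))
    data.frame(exposure = nm,
               rr_not_significant = fit$stratum_rr$not_significant$rr,
               rr_significant = fit$stratum_rr$significant$rr,
               rr_not_reported = fit$stratum_rr$not_reported$rr,
               joint_statistic = fit$joint_test_statistic,
               joint_p = fit$joint_test_p)
  }))
  .stage_log(verbose, "association", n, nrow(rr_table))

  groupings <- list(
    all = NULL,
    sig_reported = function(p) if (exposures$sig_reported(p))
      "reported" else "not_reported",
    first_coi_any = function(p) {
      e <- exposures$first_coi_any(p)
      if (is.na(e)) NA else if (e) "coi" else "no_coi"
    })
  km <- list()
  logrank_rows <- list()
  for (nm in names(groupings)) {
    recs <- to_survival_records(cohort, groupings[[nm]])
    if (nm == "all") {
      km[[nm]] <- km_estimate(recs)
    } else {
      for (g in unique(recs$group))
        km[[paste(nm, g, sep = ":")]] <-
          km_estimate(recs[recs$group == g, , drop = FALSE])
      lr <- log_rank(recs)
      logrank_rows[[nm]] <- data.frame(comparison = nm,
                                       statistic = lr$statistic,
                                       df = lr$df, p_value = lr$p_value)
    }
  }
  surv_summary <- median_iqr(to_survival_records(cohort))
  .stage_log(verbose, "survival", n, sum(published))

  assumption_table <- assumption_analysis(cohort, config$assumption_grid,
                                          seed = config$seed, alpha = alpha)
  .stage_log(verbose, "sensitivity", n, nrow(assumption_table))

  bundle <- structure(list(
    n_abstracts = n, n_published = sum(published),
    publication_proportion = mean(published),
    selection_census = census, significance_census = sig_census,
    concordance = concordance, rr_table = rr_table,
    interaction_table = interaction_table, km = km,
    logrank_table = do.call(rbind, logrank_rows),
    time_to_publication = surv_summary,
    assumption_table = assumption_table,
    config = list(alpha = alpha, seed = config$seed,
                  assumption_grid = config$assumption_grid)),
    class = "pipeline_bundle")
  if (!is.null(config$outdir)) write_results(bundle, config$outdir)
  bundle
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat(sprintf("Pipeline bundle: %d abstracts, %d published (%s%%)\n",
              x$n_abstracts, x$n_published,
              fmt_pct(100 * x$publication_proportion)))
  cat(sprintf("comparable pairs: %d; discordant (exact def.): %s%%\n",
              x$concordance$exact$n_comparable,
              fmt_pct(100 * x$concordance$exact$prop_discordant)))
  cat("risk ratios:\n")
  print(within(x$rr_table, {
    rr <- fmt_rr(rr); ci_low <- fmt_rr(ci_low); ci_high <- fmt_rr(ci_high)
  }), row.names = FALSE)
  invisible(x)
}
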