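# Shorthand constructors used across the suite.

mk_ratio <- function(value = NA_real_, p = NA_real_, ci = c(NA, NA),
                     favored = NA_character_) {
  effect_estimate("ratio_measure", value = value, ci_low = ci[1],
                  ci_high = ci[2], p_value = p, favored_arm = favored)
}

mk_outcome <- function(..., domain = "intraocular pressure", time = 6,
                       order = 1L, primary = FALSE, titled = FALSE,
                       claims = FALSE) {
  outcome_report(domain = domain, time_value = time, time_unit = "months",
                 is_primary = primary, in_title_or_objective = titled,
                 results_order = order, comparisons = list(...),
                 claims_significance_without_data = claims)
}

# Minimal pair record with a given main-outcome significance class,
# first-author COI status, and publication status. Used to build cohorts
# with exact cell counts for the association tests.
mk_pair <- function(cls = "significant", coi = FALSE, published = TRUE,
                    year = 2002L, months = 12L, id = "x") {
  cmp <- switch(cls,
                significant = mk_ratio(1.5, p = 0.01),
                not_significant = mk_ratio(1.05, p = 0.4),
                not_reported = mk_ratio(1.2))
  first <- coi_profile(financial_support = coi)
  abstract <- abstract_record(id, year, authors = list(a1 = first),
                              outcomes = list(mk_outcome(cmp)))
  publication <- if (published)
    publication_record(paste0(id, "p"), months,
                       list(mk_outcome(cmp))) else NULL
  pair_record(abstract, publication, 134L)
}

# Cohort with exact counts per (class, exposure) cell: `cells` is a data
# frame with columns cls, coi, n, n_published.
mk_cohort <- function(cells) {
  out <- list()
  k <- 0L
  for (i in seq_len(nrow(cells))) {
    for (j in seq_len(cells$n[i])) {
      k <- k + 1L
      out[[k]] <- mk_pair(cells$cls[i], cells$coi[i],
                          published = j <= cells$n_published[i],
                          id = sprintf("c%04d", k))
    }
  }
  out
}
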