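.DISCORD_LEVELS <- c("exact_agreement", "qualitative", "quant_lt10",
                     "quant_10to20", "quant_gt20", "quant_unclear",
                     "not_comparable")

#' Percent difference between two effect estimates
#'
#' Signed percent difference of the abstract's estimate relative to the
#' publication's:
#' `(estimate_abstract - estimate_publication) / estimate_publication * 100`.
#'
#' @param est_abstract effect estimate reported in the abstract.
#' @param est_publication effect estimate reported in the publication
#'   (must be nonzero).
#' @return signed percentage.
#' @export
#' @examples
#' percent_difference(1.5, 1.2)   # 25
#' percent_difference(0.9, 1.2)   # -25
percent_difference <- function(est_abstract, est_publication) {
  stopifnot(is.numeric(est_abstract), is.numeric(est_publication))
  if (any(est_publication == 0))
    stop("undefined percent difference: publication estimate is 0")
  (est_abstract - est_publication) / est_publication * 100
}

#' Match status of an abstract/publication pair
#'
#' A pair is comparable when the main outcome domain is the same (after
#' label normalization and the synonym map), the main outcomes are reported
#' at exactly the same time point (compared after conversion to days), and
#' both documents report results (an estimate, CI, or p-value) for that
#' outcome.
#'
#' @param pair a [pair_record()] with a publication.
#' @param synonyms optional synonym map passed to [normalize_domain()].
#' @return list with logicals `same_domain`, `same_time_point`,
#'   `both_report_results`, and `comparable` (their conjunction);
#'   `same_time_point` is `NA` when the domains differ.
#' @export
match_status <- function(pair, synonyms = NULL) {
  stopifnot(inherits(pair, "pair_record"))
  if (!is_published(pair))
    return(list(same_domain = NA, same_time_point = NA,
                both_report_results = NA, comparable = FALSE))
  ma <- main_outcome(pair$abstract)
  mp <- main_outcome(pair$publication)
  same_domain <- identical(normalize_domain(ma$domain, synonyms),
                           normalize_domain(mp$domain, synonyms))
  same_time <- if (!same_domain) NA else {
    !is.na(ma$time_value) && !is.na(mp$time_value) &&
      isTRUE(all.equal(time_in_days(ma$time_value, ma$time_unit),
                       time_in_days(mp$time_value, mp$time_unit)))
  }
  reports <- function(o) {
    any(vapply(o$comparisons, function(cmp) {
      !all(is.na(cmp$value)) || !is.na(cmp$p_value) ||
        (!is.na(cmp$ci_low) && !is.na(cmp$ci_high))
    }, logical(1)))
  }
  both_report <- reports(ma) && reports(mp)
  list(same_domain = same_domain, same_time_point = same_time,
       both_report_results = both_report,
       comparable = same_domain && isTRUE(same_time) && both_report)
}

# Reduce a comparison to a single between-arm estimate and its measure
# family. arm_summary_pair becomes a difference (arm1 - arm2). Returns
# list(kind, value) with value NA when no estimate is recoverable.
.between_arm_estimate <- function(cmp) {
  if (cmp$kind == "arm_summary_pair") {
    if (length(cmp$value) == 2L && !anyNA(cmp$value))
      return(list(kind = "difference_measure",
                  value = cmp$value[1] - cmp$value[2]))
    return(list(kind = "difference_measure", value = NA_real_))
  }
  list(kind = cmp$kind, value = cmp$value)
}

# First comparison carrying a recoverable between-arm estimate, else NULL.
.primary_estimate <- function(report) {
  for (cmp in report$comparisons) {
    est <- .between_arm_estimate(cmp)
    if (!is.na(est$value)) return(est)
  }
  NULL
}

# First reported p-value of a report, else NA.
.primary_p <- function(report) {
  for (cmp in report$comparisons) if (!is.na(cmp$p_value)) return(cmp$p_value)
  NA_real_
}

# Direction of an effect: side of the null (1 for ratio measures, 0 for
# difference measures).
.effect_direction <- function(est) {
  null_value <- if (est$kind == "ratio_measure") 1 else 0
  sign(est$value - null_value)
}

.discordance_result <- function(category, pd = NA_real_, reason = NA_character_) {
  structure(list(category = category, percent_difference = pd,
                 reason = reason),
            class = "discordance_result")
}

#' Classify the discordance of a comparable abstract/publication pair
#'
#' Compares the main-outcome results reported in the two documents:
#' * **qualitative** discordance — the direction of the effect estimate
#'   flips, the significance status at the 5% level flips, or a different
#'   arm is significantly favored;
#' * otherwise **quantitative** discordance banded by the absolute percent
#'   difference of the estimates (`< 10`, `10--20` closed, `> 20`%), with
#'   **exact agreement** when the estimates are equal at the coarser of the
#'   two reported precisions;
#' * **quantitative, amount unclear** — only p-values are comparable and
#'   they differ without crossing the significance boundary, or the two
#'   documents report estimates on incommensurable measures.
#'
#' Pairs in which either document's main-outcome significance classifies as
#' `not_reported`, or whose match status fails, are `not_comparable`.
#'
#' @param abstract_main main [outcome_report()] of the abstract.
#' @param publication_main main [outcome_report()] of the publication.
#' @param alpha significance level for the qualitative flip test.
#' @param band_edges two increasing percent-difference band edges; the
#'   middle band is closed on both sides.
#' @return a `discordance_result`: list with `category`,
#'   `percent_difference` (signed; present for exact agreement and the
#'   banded quantitative categories), and `reason` for non-comparable pairs.
#' @export
classify_pair <- function(abstract_main, publication_main, alpha = 0.05,
                          band_edges = c(10, 20)) {
  stopifnot(inherits(abstract_main, "outcome_report"),
            inherits(publication_main, "outcome_report"),
            length(band_edges) == 2L, band_edges[1] < band_edges[2])
  sig_a <- classify_outcome(abstract_main, alpha)
  sig_p <- classify_outcome(publication_main, alpha)
  if (sig_a == "not_reported" || sig_p == "not_reported")
    return(.discordance_result("not_comparable",
                               reason = "significance not reported in both documents"))

  # Qualitative: flip of 5%-level significance status.
  if (xor(sig_a == "significant", sig_p == "significant"))
    return(.discordance_result("qualitative"))

  est_a <- .primary_estimate(abstract_main)
  est_p <- .primary_estimate(publication_main)

  if (!is.null(est_a) && !is.null(est_p)) {
    # Qualitative: a different arm significantly favored.
    fav_a <- abstract_main$comparisons[[1]]$favored_arm
    fav_p <- publication_main$comparisons[[1]]$favored_arm
    if (sig_a == "significant" && !is.na(fav_a) && !is.na(fav_p) &&
        fav_a != fav_p)
      return(.discordance_result("qualitative"))
    if (est_a$kind != est_p$kind)
      return(.discordance_result("quant_unclear",
                                 reason = "estimates on different measures"))
    # Qualitative: direction of effect flips.
    if (.effect_direction(est_a) * .effect_direction(est_p) < 0)
      return(.discordance_result("qualitative"))
    pd <- percent_difference(est_a$value, est_p$value)
    d <- min(.decimals_needed(est_a$value), .decimals_needed(est_p$value))
    if (isTRUE(all.equal(round(est_a$value, d), round(est_p$value, d))))
      return(.discordance_result("exact_agreement", pd = pd))
    apd <- abs(pd)
    cat <- if (apd < band_edges[1]) "quant_lt10"
    else if (apd <= band_edges[2]) "quant_10to20"
    else "quant_gt20"
    return(.discordance_result(cat, pd = pd))
  }

  # No estimate pair: fall back to p-values alone.
  p_a <- .primary_p(abstract_main)
  p_p <- .primary_p(publication_main)
  if (!is.na(p_a) && !is.na(p_p)) {
    if (p_a == p_p)
      return(.discordance_result("exact_agreement", pd = 0))
    return(.discordance_result("quant_unclear",
                               reason = "only p-values comparable"))
  }
  .discordance_result("quant_unclear",
                      reason = "estimates not comparable")
}

#' Summarize concordance over a cohort
#'
#' Selects main outcomes, evaluates [match_status()] per published pair,
#' classifies every comparable pair with [classify_pair()], and tallies the
#' categories. Two agreement definitions are supported: `exact` (only exact
#' agreement counts as agreement) and `exact_or_lt10` (quantitative
#' discordance below 10% also counts as agreement).
#'
#' @param pairs nonempty list of [pair_record()]s.
#' @param agreement_definition `"exact"` or `"exact_or_lt10"`.
#' @param alpha significance level.
#' @param synonyms optional domain synonym map.
#' @return list with `counts` (named vector over the discordance
#'   categories, over comparable pairs), `n_comparable`, `n_agree`,
#'   `n_discordant`, `prop_agree`, `prop_discordant`, and the definition
#'   used; class `concordance_summary`.
#' @export
summarize_concordance <- function(pairs,
                                  agreement_definition = c("exact",
                                                           "exact_or_lt10"),
                                  alpha = 0.05, synonyms = NULL) {
  if (length(pairs) == 0L) stop("no pairs supplied")
  agreement_definition <- match.arg(agreement_definition)
  cats <- vapply(pairs, function(pair) {
    ms <- match_status(pair, synonyms)
    if (!isTRUE(ms$comparable)) return("not_comparable")
    classify_pair(main_outcome(pair$abstract),
                  main_outcome(pair$publication), alpha = alpha)$category
  }, character(1))
  comparable <- cats[cats != "not_comparable"]
  counts <- vapply(setdiff(.DISCORD_LEVELS, "not_comparable"),
                   function(l) sum(comparable == l), integer(1))
  agree_levels <- if (agreement_definition == "exact") "exact_agreement"
  else c("exact_agreement", "quant_lt10")
  n_comp <- length(comparable)
  n_agree <- sum(counts[agree_levels])
  structure(list(counts = counts, n_comparable = n_comp,
                 n_agree = n_agree, n_discordant = n_comp - n_agree,
                 prop_agree = if (n_comp > 0) n_agree / n_comp else NA_real_,
                 prop_discordant = if (n_comp > 0)
                   (n_comp - n_agree) / n_comp else NA_real_,
                 agreement_definition = agreement_definition),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("Concordance over %d comparable pairs (definition: %s)\n",
              x$n_comparable, x$agreement_definition))
  print(x$counts)
  cat(sprintf("agreement: %d (%s%%), discordance: %d (%s%%)\n", x$n_agree,
              fmt_pct(100 * x$prop_agree), x$n_discordant,
              fmt_pct(100 * x$prop_discordant)))
  invisible(x)
}
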