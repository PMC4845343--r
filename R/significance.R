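.SIG_LEVELS <- c("significant", "not_significant", "not_reported")

# Interpret a single between-arm comparison at level alpha.
# Returns "sig", "nonsig", or "uninformative".
# Precedence: a reported p-value decides; otherwise a CI relative to the
# null value of the measure (1 for ratio measures, 0 for difference
# measures); otherwise an explicit statement that an arm was significantly
# favored counts as a significance indication with data. CI endpoints are
# closed: an endpoint exactly at the null is not significant by that
# criterion.
.interpret_comparison <- function(cmp, alpha) {
  if (!is.na(cmp$p_value))
    return(if (cmp$p_value < alpha) "sig" else "nonsig")
  if (!is.na(cmp$ci_low) && !is.na(cmp$ci_high)) {
    null_value <- switch(cmp$kind,
                         ratio_measure = 1,
                         difference_measure = 0,
                         arm_summary_pair = NA_real_)
    if (!is.na(null_value)) {
      return(if (cmp$ci_low > null_value || cmp$ci_high < null_value)
        "sig" else "nonsig")
    }
  }
  if (!is.na(cmp$favored_arm) && nzchar(cmp$favored_arm)) return("sig")
  "uninformative"
}

#' Classify the statistical significance of an outcome report
#'
#' Three-level classification of a reported result:
#' * `significant` — at least one reported between-arm comparison indicates
#'   statistical significance at level `alpha` (by p-value, by a confidence
#'   interval excluding the null value of its measure, or by an explicit
#'   significantly-favored-arm statement accompanying reported data);
#' * `not_significant` — every reported comparison is interpretable and
#'   non-significant;
#' * `not_reported` — insufficient data, including the case where the
#'   authors claim significance without reporting an estimate, CI, or
#'   p-value.
#'
#' The p-value comparison is strict (`p < alpha`), so `p = 0.05` at the
#' default level classifies as not significant.
#'
#' @param report an [outcome_report()].
#' @param alpha significance level in (0, 1); default 0.05.
#' @return one of `"significant"`, `"not_significant"`, `"not_reported"`.
#' @export
#' @examples
#' rep <- outcome_report("iop", 6, results_order = 1, comparisons = list(
#'   effect_estimate("ratio_measure", 1.4, p_value = 0.20),
#'   effect_estimate("ratio_measure", 1.8, p_value = 0.03)))
#' classify_outcome(rep)  # "significant": at least one comparison qualifies
classify_outcome <- function(report, alpha = 0.05) {
  stopifnot(inherits(report, "outcome_report"))
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  if (length(report$comparisons) == 0L) return("not_reported")
  calls <- vapply(report$comparisons, .interpret_comparison, character(1),
                  alpha = alpha)
  if (any(calls == "sig")) return("significant")
  if (all(calls == "nonsig")) return("not_significant")
  "not_reported"
}

#' Classify significance over all outcomes of a document
#'
#' Aggregates per-outcome classifications under the dominance order
#' significant > not_significant > not_reported, mirroring the "at least
#' one outcome" logic: the document is `significant` if any outcome is,
#' `not_significant` if none is significant but at least one is
#' interpretable, and `not_reported` otherwise.
#'
#' @param document an [abstract_record()] or [publication_record()] (or any
#'   list with an `outcomes` field).
#' @param alpha significance level.
#' @return one of `"significant"`, `"not_significant"`, `"not_reported"`.
#' @export
classify_any_outcome <- function(document, alpha = 0.05) {
  outcomes <- document$outcomes
  if (length(outcomes) == 0L) stop("document has no outcomes")
  classes <- vapply(outcomes, classify_outcome, character(1), alpha = alpha)
  if (any(classes == "significant")) return("significant")
  if (any(classes == "not_significant")) return("not_significant")
  "not_reported"
}

#' Main-outcome significance classification of an abstract
#'
#' @param pair a [pair_record()].
#' @param alpha significance level.
#' @return classification of the abstract's main outcome.
#' @export
abstract_main_significance <- function(pair, alpha = 0.05) {
  classify_outcome(main_outcome(pair$abstract), alpha = alpha)
}
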