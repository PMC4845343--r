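#' Select the main outcome of a document
#'
#' Applies a four-rule hierarchy to identify the single "main" outcome of an
#' abstract or publication:
#'
#' 1. If exactly one outcome is designated primary, select it.
#' 2. If more than one outcome is designated primary, select the one reported
#'    first in the Results section.
#' 3. If no outcome is designated primary, select the outcome mentioned in
#'    the Title or Objective (the earliest-reported one if several are).
#' 4. Otherwise select the outcome reported first in the Results section.
#'
#' The lowest-numbered applicable rule fires; order of first appearance in
#' Results (`results_order`), not list position, breaks ties, so the choice
#' is invariant to permutation of the outcomes list.
#'
#' @param outcomes nonempty list of [outcome_report()]s with unique
#'   `results_order`.
#' @return list with `outcome_index` (index into `outcomes`) and
#'   `rule_applied` (1--4), class `main_outcome_choice`.
#' @export
#' @examples
#' o1 <- outcome_report("iop", 6, results_order = 1,
#'                      comparisons = list(effect_estimate("ratio_measure", 1.2,
#'                                                         p_value = 0.04)))
#' o2 <- outcome_report("visual acuity", 6, results_order = 2, is_primary = TRUE,
#'                      comparisons = list(effect_estimate("ratio_measure", 1.1,
#'                                                         p_value = 0.50)))
#' select_main_outcome(list(o1, o2))  # rule 1 picks the designated primary
select_main_outcome <- function(outcomes) {
  if (length(outcomes) == 0L) stop("no outcomes reported")
  ord <- vapply(outcomes, function(o) o$results_order, integer(1))
  if (anyDuplicated(ord))
    stop("results_order values must be unique; cannot break the tie")
  primary <- which(vapply(outcomes, function(o) o$is_primary, logical(1)))
  titled <- which(vapply(outcomes, function(o) o$in_title_or_objective,
                         logical(1)))
  if (length(primary) == 1L) {
    idx <- primary; rule <- 1L
  } else if (length(primary) > 1L) {
    idx <- primary[which.min(ord[primary])]; rule <- 2L
  } else if (length(titled) >= 1L) {
    idx <- titled[which.min(ord[titled])]; rule <- 3L
  } else {
    idx <- which.min(ord); rule <- 4L
  }
  structure(list(outcome_index = idx, rule_applied = rule),
            class = "main_outcome_choice")
}

#' Main outcome report of a document
#'
#' Convenience accessor: applies [select_main_outcome()] and returns the
#' chosen [outcome_report()].
#'
#' @param document an [abstract_record()] or [publication_record()].
#' @return an [outcome_report()].
#' @export
main_outcome <- function(document) {
  choice <- select_main_outcome(document$outcomes)
  document$outcomes[[choice$outcome_index]]
}

#' Census of selection rules over a cohort
#'
#' Tallies which selection rule identified the main outcome of each abstract.
#'
#' @param cohort nonempty list of [pair_record()]s.
#' @return named integer vector of counts for rules 1--4 (sums to the cohort
#'   size), with a `proportion` attribute.
#' @export
selection_rule_census <- function(cohort) {
  if (length(cohort) == 0L) stop("empty cohort")
  rules <- vapply(cohort, function(p)
    select_main_outcome(p$abstract$outcomes)$rule_applied, integer(1))
  counts <- vapply(1:4, function(r) sum(rules == r), integer(1))
  names(counts) <- paste0("rule", 1:4)
  attr(counts, "proportion") <- counts / length(cohort)
  counts
}
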