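#' @title Cohort record types
#' @description
#' The cohort is represented by plain S3 lists mirroring how a meta-research
#' team extracts data: a document (conference abstract or journal
#' publication) carries a list of outcome reports, each outcome report
#' carries one effect estimate per between-arm comparison, and an abstract is
#' linked to its earliest publication (if any) in a pair record.
#' @name trialpub-records
NULL

.EFFECT_KINDS <- c("ratio_measure", "difference_measure", "arm_summary_pair")
.FUNDING_LEVELS <- c("industry", "government", "other", "none", "not_reported")
.CENTER_LEVELS <- c("single", "multi", "not_reported")
.PRESENTATION_LEVELS <- c("poster", "oral")
.DISCLOSURE_LEVELS <- c("per_author", "team_aggregate", "not_reported")

# The six disclosure categories used by the conference's COI system.
COI_FLAGS <- c("financial_support", "personal_financial_interest",
               "employee_of_business", "consultant_to_business",
               "inventor_with_patent", "received_gifts")

#' Effect estimate for one between-arm comparison
#'
#' @param kind one of `"ratio_measure"` (RR/OR/HR; null value 1),
#'   `"difference_measure"` (null value 0), or `"arm_summary_pair"` (two
#'   per-arm summaries, reduced to a difference when a between-arm estimate
#'   is needed).
#' @param value the between-arm estimate, or a length-2 numeric of per-arm
#'   summaries for `arm_summary_pair`. May be `NA` when only a p-value was
#'   reported.
#' @param ci_low,ci_high optional 95% confidence limits.
#' @param p_value optional p-value in `[0, 1]`.
#' @param favored_arm optional arm identifier that the document states was
#'   statistically significantly favored.
#' @param direction_sign optional -1/0/+1 direction indicator, for documents
#'   reporting a direction without a numeric estimate.
#' @return an object of class `effect_estimate`.
#' @export
effect_estimate <- function(kind, value = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, p_value = NA_real_,
                            favored_arm = NA_character_,
                            direction_sign = NA_integer_) {
  kind <- match.arg(kind, .EFFECT_KINDS)
  value <- as.numeric(value)
  if (kind == "arm_summary_pair") {
    if (!all(is.na(value)) && length(value) != 2L)
      stop("arm_summary_pair requires a length-2 value (per-arm summaries)")
  } else if (length(value) != 1L) {
    stop("value must be a single number for kind ", kind)
  }
  if (!is.na(ci_low) && !is.na(ci_high) && ci_low > ci_high)
    stop("ci_low must not exceed ci_high")
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop("p_value must lie in [0, 1]")
  if (kind == "ratio_measure" && !is.na(value) && value <= 0)
    stop("ratio_measure estimates must be positive")
  if (!is.na(direction_sign) && !direction_sign %in% c(-1L, 0L, 1L))
    stop("direction_sign must be -1, 0, or +1")
  structure(list(kind = kind, value = value,
                 ci_low = as.numeric(ci_low), ci_high = as.numeric(ci_high),
                 p_value = as.numeric(p_value),
                 favored_arm = as.character(favored_arm),
                 direction_sign = as.integer(direction_sign)),
            class = "effect_estimate")
}

#' One outcome as reported in one document
#'
#' @param domain outcome-domain label (free text; normalized on comparison).
#' @param time_value,time_unit the time point at which results are reported.
#' @param is_primary was the outcome designated primary by the authors?
#' @param in_title_or_objective is the outcome mentioned in the title or
#'   objective?
#' @param results_order order of first appearance in the Results section
#'   (positive integer, unique within a document).
#' @param comparisons list of [effect_estimate()] objects, one per reported
#'   between-arm comparison.
#' @param claims_significance_without_data `TRUE` when the authors state the
#'   result was statistically significant without reporting an estimate, CI,
#'   or p-value.
#' @return an object of class `outcome_report`.
#' @export
outcome_report <- function(domain, time_value = NA_real_,
                           time_unit = "months", is_primary = FALSE,
                           in_title_or_objective = FALSE, results_order,
                           comparisons = list(),
                           claims_significance_without_data = FALSE) {
  stopifnot(.is_flag(is_primary), .is_flag(in_title_or_objective),
            .is_flag(claims_significance_without_data))
  if (!.is_count(results_order) || results_order < 1)
    stop("results_order must be a positive integer")
  if (!all(vapply(comparisons, inherits, logical(1), "effect_estimate")))
    stop("comparisons must be a list of effect_estimate objects")
  if (length(comparisons) == 0L && !claims_significance_without_data)
    stop("an outcome report needs comparisons or a significance claim")
  structure(list(domain = as.character(domain),
                 time_value = as.numeric(time_value),
                 time_unit = as.character(time_unit),
                 is_primary = is_primary,
                 in_title_or_objective = in_title_or_objective,
                 results_order = as.integer(results_order),
                 comparisons = comparisons,
                 claims_significance_without_data =
                   claims_significance_without_data),
            class = "outcome_report")
}

#' Conflict-of-interest profile for one author
#'
#' The six boolean categories follow the conference's disclosure system.
#' `disclosure_level` records whether the profile was disclosed per author,
#' aggregated over the author team (permitted only for the 2001 cohort year,
#' when only team-level disclosure was collected), or not reported.
#'
#' @param financial_support,personal_financial_interest,employee_of_business,consultant_to_business,inventor_with_patent,received_gifts logical flags.
#' @param disclosure_level one of `"per_author"`, `"team_aggregate"`,
#'   `"not_reported"`.
#' @return an object of class `coi_profile`.
#' @export
coi_profile <- function(financial_support = FALSE,
                        personal_financial_interest = FALSE,
                        employee_of_business = FALSE,
                        consultant_to_business = FALSE,
                        inventor_with_patent = FALSE,
                        received_gifts = FALSE,
                        disclosure_level = "per_author") {
  flags <- list(financial_support = financial_support,
                personal_financial_interest = personal_financial_interest,
                employee_of_business = employee_of_business,
                consultant_to_business = consultant_to_business,
                inventor_with_patent = inventor_with_patent,
                received_gifts = received_gifts)
  stopifnot(all(vapply(flags, .is_flag, logical(1))))
  disclosure_level <- match.arg(disclosure_level, .DISCLOSURE_LEVELS)
  structure(c(flags, list(disclosure_level = disclosure_level)),
            class = "coi_profile")
}

#' Does a COI profile report at least one conflict?
#' @param profile a [coi_profile()].
#' @return logical.
#' @export
has_any_coi <- function(profile) {
  any(unlist(profile[COI_FLAGS]))
}

#' Conference abstract record
#'
#' @param abstract_id unique identifier.
#' @param conference_year integer cohort year.
#' @param presentation `"poster"` or `"oral"`.
#' @param funding character vector over industry/government/other/none/
#'   not_reported; `none` and `not_reported` are only valid as singletons.
#' @param centers `"single"`, `"multi"`, or `"not_reported"`.
#' @param authors named list of [coi_profile()]s in author order (names are
#'   author identifiers).
#' @param outcomes list of [outcome_report()]s.
#' @return an object of class `abstract_record`.
#' @export
abstract_record <- function(abstract_id, conference_year,
                            presentation = "poster",
                            funding = "not_reported",
                            centers = "not_reported", authors, outcomes) {
  if (is.na(abstract_id) || !nzchar(abstract_id))
    stop("abstract_id is required")
  presentation <- match.arg(presentation, .PRESENTATION_LEVELS)
  centers <- match.arg(centers, .CENTER_LEVELS)
  if (!all(funding %in% .FUNDING_LEVELS))
    stop("unknown funding value: ",
         paste(setdiff(funding, .FUNDING_LEVELS), collapse = ", "))
  if (any(c("none", "not_reported") %in% funding) && length(funding) > 1L)
    stop("funding 'none'/'not_reported' must be a singleton")
  if (length(authors) == 0L)
    stop("authors must be nonempty")
  if (!all(vapply(authors, inherits, logical(1), "coi_profile")))
    stop("authors must be a list of coi_profile objects")
  if (is.null(names(authors)) || any(!nzchar(names(authors))))
    names(authors) <- sprintf("author%02d", seq_along(authors))
  team <- vapply(authors, function(a) a$disclosure_level, character(1))
  if (any(team == "team_aggregate") && conference_year != 2001L)
    stop("team_aggregate COI disclosure is only permitted for cohort year 2001")
  if (!all(vapply(outcomes, inherits, logical(1), "outcome_report")))
    stop("outcomes must be a list of outcome_report objects")
  ord <- vapply(outcomes, function(o) o$results_order, integer(1))
  if (anyDuplicated(ord))
    stop("results_order must be unique within a document (abstract ",
         abstract_id, ")")
  structure(list(abstract_id = as.character(abstract_id),
                 conference_year = as.integer(conference_year),
                 presentation = presentation, funding = funding,
                 centers = centers, authors = authors, outcomes = outcomes),
            class = "abstract_record")
}

#' Full-publication record
#'
#' @param publication_id identifier.
#' @param months_after_presentation integer months from conference
#'   presentation to publication; publication before or at presentation is
#'   coded 1 (the within-one-month convention).
#' @param outcomes list of [outcome_report()]s.
#' @return an object of class `publication_record`.
#' @export
publication_record <- function(publication_id, months_after_presentation,
                               outcomes) {
  if (is.na(publication_id) || !nzchar(publication_id))
    stop("publication_id is required")
  if (!.is_count(months_after_presentation) || months_after_presentation < 1)
    stop("months_after_presentation must be an integer >= 1 ",
         "(code pre-presentation publication as 1)")
  if (!all(vapply(outcomes, inherits, logical(1), "outcome_report")))
    stop("outcomes must be a list of outcome_report objects")
  ord <- vapply(outcomes, function(o) o$results_order, integer(1))
  if (anyDuplicated(ord))
    stop("results_order must be unique within a document (publication ",
         publication_id, ")")
  structure(list(publication_id = as.character(publication_id),
                 months_after_presentation =
                   as.integer(months_after_presentation),
                 outcomes = outcomes),
            class = "publication_record")
}

#' Abstract linked to its earliest publication (or none)
#'
#' @param abstract an [abstract_record()].
#' @param publication an optional [publication_record()].
#' @param followup_months search-cutoff horizon (months) for this abstract's
#'   cohort year; censoring time for unpublished abstracts.
#' @return an object of class `pair_record`.
#' @export
pair_record <- function(abstract, publication = NULL, followup_months) {
  stopifnot(inherits(abstract, "abstract_record"))
  if (!is.null(publication))
    stopifnot(inherits(publication, "publication_record"))
  if (!.is_count(followup_months) || followup_months < 1)
    stop("followup_months must be a positive integer")
  if (!is.null(publication) &&
      followup_months < publication$months_after_presentation)
    stop("followup_months must be >= months_after_presentation")
  structure(list(abstract = abstract, publication = publication,
                 followup_months = as.integer(followup_months)),
            class = "pair_record")
}

#' Was the abstract in a pair published?
#' @param pair a [pair_record()].
#' @return logical.
#' @export
is_published <- function(pair) !is.null(pair$publication)

#' @export
print.pair_record <- function(x, ...) {
  cat(sprintf("<pair_record %s (%d): %s, followup %d months>\n",
              x$abstract$abstract_id, x$abstract$conference_year,
              if (is_published(x))
                sprintf("published at month %d",
                        x$publication$months_after_presentation)
              else "unpublished",
              x$followup_months))
  invisible(x)
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate %s: value=%s, CI (%s, %s), p=%s>\n",
              x$kind, paste(signif(x$value, 4), collapse = "/"),
              signif(x$ci_low, 4), signif(x$ci_high, 4),
              signif(x$p_value, 4)))
  invisible(x)
}
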