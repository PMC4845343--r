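#' @title Cohort file formats
#' @description
#' Two equivalent on-disk layouts are supported. The CSV layout is "long":
#' one row per (pair, document, outcome, comparison), with pair-level
#' metadata repeated on every row, which keeps the schema diff-able and
#' easy to build by hand. The JSON layout nests the same fields naturally.
#' A written cohort reads back identical on all fields (round-trip
#' property). The only silent coercion on read is the documented
#' publication-timing convention: `months_after_presentation < 1` (a
#' publication before or at presentation) is coerced to 1 with a note.
#' @name trialpub-io
NULL

.COI_LETTERS <- c(financial_support = "F", personal_financial_interest = "P",
                  employee_of_business = "E", consultant_to_business = "C",
                  inventor_with_patent = "I", received_gifts = "G")
.DISCLOSURE_LETTERS <- c(per_author = "p", team_aggregate = "t",
                         not_reported = "n")

.encode_authors <- function(authors) {
  paste(vapply(names(authors), function(id) {
    a <- authors[[id]]
    flags <- paste(.COI_LETTERS[unlist(a[COI_FLAGS])], collapse = "")
    sprintf("%s=%s@%s", id, flags,
            .DISCLOSURE_LETTERS[[a$disclosure_level]])
  }, character(1)), collapse = "|")
}

.decode_authors <- function(encoded) {
  parts <- strsplit(encoded, "|", fixed = TRUE)[[1]]
  authors <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^([^=]+)=([FPECIG]*)@([ptn])$", p))[[1]]
    if (length(m) != 4L) stop("malformed author encoding: ", p)
    flags <- as.list(names(.COI_LETTERS) %in%
                       names(.COI_LETTERS)[match(strsplit(m[3], "")[[1]],
                                                 .COI_LETTERS)])
    names(flags) <- names(.COI_LETTERS)
    level <- names(.DISCLOSURE_LETTERS)[.DISCLOSURE_LETTERS == m[4]]
    do.call(coi_profile, c(flags, list(disclosure_level = level)))
  })
  ids <- vapply(parts, function(p) sub("=.*$", "", p), character(1))
  names(authors) <- ids
  authors
}

.outcome_rows <- function(outcome, document) {
  base <- data.frame(
    document = document, domain = outcome$domain,
    time_value = outcome$time_value, time_unit = outcome$time_unit,
    is_primary = outcome$is_primary,
    in_title_or_objective = outcome$in_title_or_objective,
    results_order = outcome$results_order,
    claims_significance_without_data =
      outcome$claims_significance_without_data,
    stringsAsFactors = FALSE)
  if (length(outcome$comparisons) == 0L) {
    return(cbind(base, data.frame(comparison_index = NA_integer_,
                                  kind = NA_character_, value = NA_real_,
                                  value2 = NA_real_, ci_low = NA_real_,
                                  ci_high = NA_real_, p_value = NA_real_,
                                  favored_arm = NA_character_,
                                  direction_sign = NA_integer_)))
  }
  do.call(rbind, lapply(seq_along(outcome$comparisons), function(j) {
    cmp <- outcome$comparisons[[j]]
    v <- cmp$value
    cbind(base, data.frame(
      comparison_index = j, kind = cmp$kind,
      value = if (length(v) >= 1) v[1] else NA_real_,
      value2 = if (length(v) == 2) v[2] else NA_real_,
      ci_low = cmp$ci_low, ci_high = cmp$ci_high, p_value = cmp$p_value,
      favored_arm = cmp$favored_arm, direction_sign = cmp$direction_sign,
      stringsAsFactors = FALSE))
  }))
}

.pair_rows <- function(pair) {
  ab <- pair$abstract
  meta <- data.frame(
    abstract_id = ab$abstract_id, conference_year = ab$conference_year,
    presentation = ab$presentation,
    funding = paste(ab$funding, collapse = ";"), centers = ab$centers,
    authors = .encode_authors(ab$authors),
    followup_months = pair$followup_months,
    publication_id = if (is_published(pair))
      pair$publication$publication_id else NA_character_,
    months_after_presentation = if (is_published(pair))
      pair$publication$months_after_presentation else NA_integer_,
    stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(ab$outcomes, .outcome_rows, "abstract"))
  if (is_published(pair))
    rows <- rbind(rows, do.call(rbind, lapply(pair$publication$outcomes,
                                              .outcome_rows, "publication")))
  cbind(meta[rep(1L, nrow(rows)), , drop = FALSE], rows,
        row.names = NULL)
}

#' Write a cohort to disk
#'
#' @param cohort list of [pair_record()]s.
#' @param path output file path.
#' @param format `"csv"` (long layout) or `"json"` (nested).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    rows <- do.call(rbind, lapply(cohort, .pair_rows))
    utils::write.csv(rows, path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(lapply(cohort, .pair_json), path,
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  }
  invisible(path)
}

.pair_json <- function(pair) {
  outcome_json <- function(o) {
    list(domain = o$domain, time_value = o$time_value,
         time_unit = o$time_unit, is_primary = o$is_primary,
         in_title_or_objective = o$in_title_or_objective,
         results_order = o$results_order,
         claims_significance_without_data =
           o$claims_significance_without_data,
         comparisons = lapply(o$comparisons, function(cmp)
           list(kind = cmp$kind, value = cmp$value, ci_low = cmp$ci_low,
                ci_high = cmp$ci_high, p_value = cmp$p_value,
                favored_arm = cmp$favored_arm,
                direction_sign = cmp$direction_sign)))
  }
  ab <- pair$abstract
  list(abstract = list(
    abstract_id = ab$abstract_id, conference_year = ab$conference_year,
    presentation = ab$presentation, funding = as.list(ab$funding),
    centers = ab$centers,
    authors = lapply(ab$authors, function(a)
      c(a[COI_FLAGS], list(disclosure_level = a$disclosure_level))),
    outcomes = lapply(ab$outcomes, outcome_json)),
    publication = if (is_published(pair)) list(
      publication_id = pair$publication$publication_id,
      months_after_presentation =
        pair$publication$months_after_presentation,
      outcomes = lapply(pair$publication$outcomes, outcome_json)) else NULL,
    followup_months = pair$followup_months)
}

.num_or_na <- function(x) if (is.null(x) || length(x) == 0L) NA_real_ else as.numeric(x)
.chr_or_na <- function(x) if (is.null(x) || length(x) == 0L) NA_character_ else as.character(x)
.int_or_na <- function(x) if (is.null(x) || length(x) == 0L) NA_integer_ else as.integer(x)

.outcome_from_json <- function(o) {
  comparisons <- lapply(o$comparisons, function(cmp) {
    value <- if (is.null(cmp$value)) NA_real_ else {
      v <- as.numeric(unlist(cmp$value))
      if (length(v) == 0L) NA_real_ else v
    }
    effect_estimate(kind = cmp$kind,
                    value = value,
                    ci_low = .num_or_na(cmp$ci_low),
                    ci_high = .num_or_na(cmp$ci_high),
                    p_value = .num_or_na(cmp$p_value),
                    favored_arm = .chr_or_na(cmp$favored_arm),
                    direction_sign = .int_or_na(cmp$direction_sign))
  })
  outcome_report(domain = o$domain, time_value = .num_or_na(o$time_value),
                 time_unit = o$time_unit, is_primary = o$is_primary,
                 in_title_or_objective = o$in_title_or_objective,
                 results_order = o$results_order, comparisons = comparisons,
                 claims_significance_without_data =
                   o$claims_significance_without_data)
}

.coerce_months <- function(months, id) {
  if (!is.na(months) && months < 1) {
    message("note: ", id, " published before or at presentation; ",
            "months_after_presentation coerced to 1")
    months <- 1L
  }
  months
}

#' Read a cohort from disk
#'
#' Parses the long-CSV or nested-JSON cohort layout (see
#' [trialpub-io]) and validates every record. Malformed records are
#' collected and reported together with their row index (CSV) or element
#' index (JSON). Publication months below 1 are coerced to 1 with a note
#' (the within-one-month convention); nothing else is silently coerced.
#'
#' @param path input file.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @return list of [pair_record()]s.
#' @export
read_cohort <- function(path, format = c("csv", "json")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (length(format) > 1L)
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
  else "csv"
  format <- match.arg(format, c("csv", "json"))
  if (format == "json") return(.read_cohort_json(path))
  .read_cohort_csv(path)
}

.read_cohort_json <- function(path) {
  raw <- jsonlite::read_json(path)
  errors <- character(0)
  out <- vector("list", length(raw))
  for (i in seq_along(raw)) {
    out[[i]] <- tryCatch({
      p <- raw[[i]]
      ab <- p$abstract
      if (is.null(ab$abstract_id)) stop("missing abstract_id")
      authors <- lapply(ab$authors, function(a)
        do.call(coi_profile, a))
      abstract <- abstract_record(
        ab$abstract_id, ab$conference_year, ab$presentation,
        funding = unlist(ab$funding), centers = ab$centers,
        authors = authors,
        outcomes = lapply(ab$outcomes, .outcome_from_json))
      publication <- if (!is.null(p$publication)) {
        months <- .coerce_months(p$publication$months_after_presentation,
                                 p$publication$publication_id)
        publication_record(p$publication$publication_id, months,
                           lapply(p$publication$outcomes,
                                  .outcome_from_json))
      } else NULL
      pair_record(abstract, publication, p$followup_months)
    }, error = function(e) {
      errors <<- c(errors, sprintf("element %d: %s", i, conditionMessage(e)))
      NULL
    })
  }
  if (length(errors) > 0L)
    stop("cohort parse errors:\n  ", paste(errors, collapse = "\n  "))
  out
}

.read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        colClasses = c(abstract_id = "character"))
  required <- c("abstract_id", "conference_year", "presentation", "funding",
                "centers", "authors", "followup_months", "document",
                "domain", "results_order")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("cohort parse errors:\n  missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(is.na(df$abstract_id)))
    stop("cohort parse errors:\n  row ",
         paste(which(is.na(df$abstract_id)), collapse = ", "),
         ": missing abstract_id")
  df$.row <- seq_len(nrow(df))
  errors <- character(0)
  ids <- unique(df$abstract_id)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rows <- df[df$abstract_id == ids[i], , drop = FALSE]
    out[[i]] <- tryCatch(.pair_from_rows(rows),
                         error = function(e) {
                           errors <<- c(errors,
                                        sprintf("row %d (abstract %s): %s",
                                                rows$.row[1], ids[i],
                                                conditionMessage(e)))
                           NULL
                         })
  }
  if (length(errors) > 0L)
    stop("cohort parse errors:\n  ", paste(errors, collapse = "\n  "))
  out
}

.outcomes_from_rows <- function(rows) {
  lapply(split(rows, rows$results_order), function(grp) {
    grp <- grp[order(ifelse(is.na(grp$comparison_index), 1L,
                            grp$comparison_index)), , drop = FALSE]
    comparisons <- list()
    for (j in seq_len(nrow(grp))) {
      if (is.na(grp$kind[j])) next
      value <- if (grp$kind[j] == "arm_summary_pair")
        c(grp$value[j], grp$value2[j]) else grp$value[j]
      comparisons <- c(comparisons, list(effect_estimate(
        kind = grp$kind[j], value = value, ci_low = grp$ci_low[j],
        ci_high = grp$ci_high[j], p_value = grp$p_value[j],
        favored_arm = grp$favored_arm[j],
        direction_sign = grp$direction_sign[j])))
    }
    outcome_report(domain = grp$domain[1], time_value = grp$time_value[1],
                   time_unit = grp$time_unit[1],
                   is_primary = grp$is_primary[1],
                   in_title_or_objective = grp$in_title_or_objective[1],
                   results_order = grp$results_order[1],
                   comparisons = comparisons,
                   claims_significance_without_data =
                     grp$claims_significance_without_data[1])
  })
}

.pair_from_rows <- function(rows) {
  ab_rows <- rows[rows$document == "abstract", , drop = FALSE]
  pub_rows <- rows[rows$document == "publication", , drop = FALSE]
  if (nrow(ab_rows) == 0L) stop("no abstract rows")
  abstract <- abstract_record(
    abstract_id = ab_rows$abstract_id[1],
    conference_year = ab_rows$conference_year[1],
    presentation = ab_rows$presentation[1],
    funding = strsplit(ab_rows$funding[1], ";", fixed = TRUE)[[1]],
    centers = ab_rows$centers[1],
    authors = .decode_authors(ab_rows$authors[1]),
    outcomes = unname(.outcomes_from_rows(ab_rows)))
  publication <- if (nrow(pub_rows) > 0L) {
    months <- .coerce_months(pub_rows$months_after_presentation[1],
                             pub_rows$publication_id[1])
    publication_record(pub_rows$publication_id[1], months,
                       unname(.outcomes_from_rows(pub_rows)))
  } else NULL
  pair_record(abstract, publication, ab_rows$followup_months[1])
}

#' Write an analysis results bundle to disk
#'
#' Emits the bundle produced by [run_pipeline()] as a set of CSV tables
#' (selection census, significance census, concordance summary under both
#' agreement definitions, risk-ratio table, interaction table,
#' Kaplan-Meier curves, log-rank tests, assumption analysis) plus a JSON
#' file of all estimates. Output is deterministic for identical bundles:
#' fixed row ordering and fixed numeric formatting (risk ratios and CIs to
#' 2 decimals, proportions to 1 decimal).
#'
#' @param bundle a `pipeline_bundle` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
write_results <- function(bundle, dir) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("directory not writable: ", dir)
  files <- character(0)
  emit <- function(df, name) {
    f <- file.path(dir, name)
    utils::write.csv(df, f, row.names = FALSE, na = "")
    files <<- c(files, f)
  }
  emit(data.frame(rule = paste0("rule", 1:4),
                  count = as.integer(bundle$selection_census)),
       "selection_census.csv")
  emit(bundle$significance_census, "significance_census.csv")
  conc <- do.call(rbind, lapply(bundle$concordance, function(s)
    data.frame(definition = s$agreement_definition,
               category = names(s$counts), count = as.integer(s$counts),
               n_comparable = s$n_comparable,
               prop_discordant_pct = fmt_pct(100 * s$prop_discordant))))
  emit(conc, "concordance_summary.csv")
  rr <- bundle$rr_table
  rr$rr <- fmt_rr(as.numeric(rr$rr))
  rr$ci_low <- fmt_rr(as.numeric(rr$ci_low))
  rr$ci_high <- fmt_rr(as.numeric(rr$ci_high))
  emit(rr, "rr_table.csv")
  if (!is.null(bundle$interaction_table)) {
    it <- bundle$interaction_table
    for (col in c("rr_not_significant", "rr_significant", "rr_not_reported"))
      it[[col]] <- fmt_rr(as.numeric(it[[col]]))
    emit(it, "interaction_table.csv")
  }
  km <- do.call(rbind, lapply(names(bundle$km), function(g)
    cbind(group = g, as.data.frame(bundle$km[[g]]))))
  emit(km, "km_curves.csv")
  emit(bundle$logrank_table, "logrank_tests.csv")
  sens <- bundle$assumption_table
  sens$rr <- fmt_rr(as.numeric(sens$rr))
  sens$ci_low <- fmt_rr(as.numeric(sens$ci_low))
  sens$ci_high <- fmt_rr(as.numeric(sens$ci_high))
  emit(sens, "assumption_table.csv")
  json_path <- file.path(dir, "results.json")
  jsonlite::write_json(bundle[setdiff(names(bundle), "km")], json_path,
                       auto_unbox = TRUE, digits = 10, na = "null",
                       force = TRUE)
  files <- c(files, json_path)
  invisible(files)
}
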