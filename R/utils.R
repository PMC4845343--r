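`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalize an outcome-domain label
#'
#' Lower-cases, strips punctuation, collapses whitespace, and then applies an
#' optional synonym map so that mechanically different spellings of the same
#' outcome domain compare equal. The synonym map is a named character vector
#' mapping normalized variants to a canonical label; it is applied after the
#' mechanical normalization.
#'
#' @param x character vector of domain labels.
#' @param synonyms optional named character vector (`variant = canonical`).
#' @return normalized character vector.
#' @export
#' @examples
#' normalize_domain("  Intra-Ocular Pressure ")
#' normalize_domain("IOP", synonyms = c(iop = "intraocular pressure"))
normalize_domain <- function(x, synonyms = NULL) {
  out <- tolower(trimws(x))
  out <- gsub("[[:punct:]]+", " ", out)
  out <- gsub("[[:space:]]+", " ", trimws(out))
  if (!is.null(synonyms)) {
    names(synonyms) <- normalize_domain(names(synonyms))
    hit <- match(out, names(synonyms))
    out[!is.na(hit)] <- unname(synonyms[hit[!is.na(hit)]])
  }
  out
}

# Fixed conversion to days so time points compare exactly after unit
# conversion (no tolerance window).
.DAYS_PER_UNIT <- c(day = 1, days = 1, week = 7, weeks = 7,
                    month = 30.4375, months = 30.4375,
                    year = 365.25, years = 365.25)

#' Convert a time point to days
#'
#' @param value numeric time value.
#' @param unit one of day(s), week(s), month(s), year(s).
#' @return time in days.
#' @export
time_in_days <- function(value, unit) {
  unit <- tolower(unit)
  if (!unit %in% names(.DAYS_PER_UNIT))
    stop("unknown time unit: ", unit)
  value * .DAYS_PER_UNIT[[unit]]
}

# Decimal places actually needed to print x (capped), used for the
# printed-precision equality rule in the concordance module.
.decimals_needed <- function(x, max_d = 6L) {
  for (d in 0:max_d) {
    if (isTRUE(all.equal(round(x, d), x, tolerance = 1e-9))) return(d)
  }
  max_d
}

# Fixed-format numeric rendering used by all result writers (determinism).
fmt_rr <- function(x) ifelse(is.na(x), "", sprintf("%.2f", x))
fmt_pct <- function(x) ifelse(is.na(x), "", sprintf("%.1f", x))

.is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}
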