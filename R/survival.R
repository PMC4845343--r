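#' Convert a cohort to time-to-publication records
#'
#' Published abstracts contribute an event at `months_after_presentation`
#' (publication at or before presentation is already coded as month 1);
#' unpublished abstracts are censored at their cohort-year follow-up
#' horizon.
#'
#' @param cohort list of [pair_record()]s.
#' @param grouping optional `function(pair) -> label` assigning each record
#'   to a comparison group; default puts everything in one group.
#' @return data.frame with columns `time_months`, `event`, `group`.
#' @export
to_survival_records <- function(cohort, grouping = NULL) {
  if (length(cohort) == 0L) stop("empty cohort")
  rows <- lapply(cohort, function(pair) {
    if (is.na(pair$followup_months))
      stop("missing followup horizon for abstract ",
           pair$abstract$abstract_id)
    grp <- if (is.null(grouping)) "all" else as.character(grouping(pair))
    if (is_published(pair)) {
      data.frame(time_months = pair$publication$months_after_presentation,
                 event = TRUE, group = grp, stringsAsFactors = FALSE)
    } else {
      data.frame(time_months = pair$followup_months, event = FALSE,
                 group = grp, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out[!is.na(out$group), , drop = FALSE]
}

#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit estimator of the publication-free "survival"
#' function and its complement, the cumulative probability of publication.
#' Ties are handled by the standard convention that events at time t precede
#' censorings at t (both are counted in the risk set at t).
#'
#' @param records data.frame as returned by [to_survival_records()] (the
#'   `group` column is ignored).
#' @return data.frame of class `km_estimate` with one row per distinct
#'   event time: `time`, `n_risk`, `n_event`, `n_censor`, `survival`,
#'   `cum_incidence`.
#' @export
km_estimate <- function(records) {
  stopifnot(nrow(records) >= 1L)
  time <- records$time_months
  event <- records$event
  times <- sort(unique(time[event]))
  if (length(times) == 0L) {
    return(structure(data.frame(time = numeric(0), n_risk = integer(0),
                                n_event = integer(0), n_censor = integer(0),
                                survival = numeric(0),
                                cum_incidence = numeric(0)),
                     class = c("km_estimate", "data.frame")))
  }
  surv <- 1
  rows <- lapply(times, function(t) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event)
    cens <- sum(time == t & !event)
    surv <<- surv * (1 - d / n_risk)
    data.frame(time = t, n_risk = n_risk, n_event = d, n_censor = cens,
               survival = surv, cum_incidence = 1 - surv)
  })
  structure(do.call(rbind, rows), class = c("km_estimate", "data.frame"))
}

#' Log-rank test across groups
#'
#' Standard log-rank test over shared risk sets: at each distinct event
#' time the observed events per group are compared with their expectation
#' under the null of identical publication-time distributions, and the
#' quadratic form of the observed-minus-expected vector in its estimated
#' covariance gives a chi-square statistic with (groups - 1) degrees of
#' freedom.
#'
#' @param records data.frame from [to_survival_records()] with >= 2 groups.
#' @return list with `statistic`, `df`, `p_value`, `groups`.
#' @export
log_rank <- function(records) {
  groups <- sort(unique(records$group))
  k <- length(groups)
  if (k < 2L) stop("log-rank test needs at least two groups")
  time <- records$time_months
  event <- records$event
  gidx <- match(records$group, groups)
  times <- sort(unique(time[event]))
  U <- numeric(k - 1)
  V <- matrix(0, k - 1, k - 1)
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(time == t & event)
    if (n <= 1L || d == 0L) next
    n_g <- vapply(seq_len(k), function(g) sum(at_risk & gidx == g),
                  numeric(1))
    d_g <- vapply(seq_len(k), function(g) sum(time == t & event & gidx == g),
                  numeric(1))
    e_g <- d * n_g / n
    U <- U + (d_g - e_g)[seq_len(k - 1)]
    # Hypergeometric covariance of the event split at this time.
    frac <- n_g / n
    cov_t <- (diag(frac, nrow = k) - tcrossprod(frac)) *
      d * (n - d) / max(n - 1, 1)
    V <- V + cov_t[seq_len(k - 1), seq_len(k - 1), drop = FALSE]
  }
  stat <- tryCatch(drop(t(U) %*% solve(V) %*% U), error = function(e) 0)
  list(statistic = stat, df = k - 1L,
       p_value = stats::pchisq(stat, df = k - 1L, lower.tail = FALSE),
       groups = groups)
}

#' Median and interquartile range of time to publication
#'
#' Descriptive summary over published records only (censored records are
#' excluded): median, quartiles (linear interpolation between order
#' statistics), and range of the event times.
#'
#' @param records data.frame from [to_survival_records()].
#' @return list with `median`, `q25`, `q75`, `min`, `max`, `n_events`.
#' @export
median_iqr <- function(records) {
  t_event <- records$time_months[records$event]
  if (length(t_event) == 0L) stop("no publication events")
  q <- stats::quantile(t_event, probs = c(0.25, 0.5, 0.75), names = FALSE,
                       type = 7)
  list(median = q[2], q25 = q[1], q75 = q[3],
       min = min(t_event), max = max(t_event), n_events = length(t_event))
}
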