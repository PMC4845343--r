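#' Parameters of the synthetic cohort generator
#'
#' The defaults encode the cohort structure the analysis assumes: 513
#' abstracts over four conference years, marginal exposure prevalences
#' matching the published cohort tables (first-author COI 33% where
#' individually disclosed, main-outcome significance reported 44.4%,
#' significant-given-reported 51.3%, funding margins, main-outcome
#' selection-rule mix 9.6/62.0/28.5%), a log-linear publication-risk model
#' whose coefficients default to the published risk ratios, a truncated
#' log-normal time-to-publication targeted at median 18 months (IQR 11-33,
#' range 1-90), and the published discordance mixture for comparable pairs.
#'
#' @param n_abstracts cohort size.
#' @param intercept_log_risk baseline log publication probability; `NULL`
#'   solves it so the implied mean publication proportion equals
#'   `target_publication_rate` under independent covariates.
#' @param log_rr named log risk ratios of the publication model; names must
#'   be among `sig_reported`, `first_coi`, `funding_none`.
#' @param target_publication_rate overall publication proportion used to
#'   solve the intercept (default 0.448).
#' @param p_first_coi,p_sig_reported,p_sig_given_reported,p_funding marginal
#'   prevalences; `p_funding` is a named vector over
#'   `not_reported`/`none`/`funded`.
#' @param coi_flag_marginals per-flag first-author COI prevalences, used to
#'   draw specific conflicts conditional on having at least one.
#' @param rule_mix probabilities of main-outcome selection rules 1/3/4.
#' @param time_meanlog,time_sdlog,time_range log-normal time-to-publication
#'   parameters (months) and truncation range.
#' @param discordance_mix counts or weights over the six comparable-pair
#'   categories `exact`, `qualitative`, `lt10`, `10to20`, `gt20`,
#'   `unclear`.
#' @param p_same_domain probability a publication shares the abstract's
#'   main-outcome domain.
#' @param p_comparable_given_same_domain probability a same-domain pair is
#'   reported at the same time point with results in both documents.
#' @param followup_horizons named months of follow-up per cohort year.
#' @param year_weights sampling weights of the cohort years.
#' @param seed default seed.
#' @return list of class `cohort_params`.
#' @export
cohort_params <- function(n_abstracts = 513L,
                          intercept_log_risk = NULL,
                          log_rr = c(sig_reported = log(1.44),
                                     first_coi = log(1.31),
                                     funding_none = log(0.76)),
                          target_publication_rate = 0.448,
                          p_first_coi = 0.33,
                          p_sig_reported = 0.444,
                          p_sig_given_reported = 0.513,
                          p_funding = c(not_reported = 241 / 513,
                                        none = 114 / 513,
                                        funded = 158 / 513),
                          coi_flag_marginals = c(
                            financial_support = 0.188,
                            personal_financial_interest = 0.010,
                            employee_of_business = 0.043,
                            consultant_to_business = 0.108,
                            inventor_with_patent = 0.020,
                            received_gifts = 0.090),
                          rule_mix = c(rule1 = 0.096, rule3 = 0.620,
                                       rule4 = 0.285),
                          time_meanlog = log(18),
                          time_sdlog = log(3) / (2 * stats::qnorm(0.75)),
                          time_range = c(1, 90),
                          discordance_mix = c(exact = 39, qualitative = 7,
                                              lt10 = 14, `10to20` = 5,
                                              gt20 = 14, unclear = 7),
                          p_same_domain = 190 / 230,
                          p_comparable_given_same_domain = 86 / 190,
                          followup_horizons = c(`2001` = 146, `2002` = 134,
                                                `2003` = 122, `2004` = 110),
                          year_weights = c(`2001` = 113, `2002` = 400 / 3,
                                           `2003` = 400 / 3,
                                           `2004` = 400 / 3),
                          seed = 1L) {
  stopifnot(n_abstracts >= 1,
            all(c(p_first_coi, p_sig_reported, p_sig_given_reported,
                  p_same_domain, p_comparable_given_same_domain) >= 0),
            all(c(p_first_coi, p_sig_reported, p_sig_given_reported,
                  p_same_domain, p_comparable_given_same_domain) <= 1),
            all(p_funding >= 0), all(discordance_mix >= 0),
            sum(discordance_mix) > 0)
  p_funding <- p_funding / sum(p_funding)
  rule_mix <- rule_mix / sum(rule_mix)
  discordance_mix <- discordance_mix / sum(discordance_mix)
  known <- c("sig_reported", "first_coi", "funding_none")
  if (!all(names(log_rr) %in% known))
    stop("unknown publication-model covariates: ",
         paste(setdiff(names(log_rr), known), collapse = ", "))
  prev <- c(sig_reported = p_sig_reported, first_coi = p_first_coi,
            funding_none = unname(p_funding["none"]))
  if (is.null(intercept_log_risk)) {
    # Under independent covariates the implied mean publication
    # probability factorizes, so the intercept has a closed form.
    mult <- prod(1 - prev[names(log_rr)] + prev[names(log_rr)] * exp(log_rr))
    intercept_log_risk <- log(target_publication_rate / mult)
  }
  max_log_p <- intercept_log_risk + sum(pmax(log_rr, 0))
  if (max_log_p > 0)
    stop("publication model implies probability > 1 (max p = ",
         signif(exp(max_log_p), 4), "); rescale the coefficients")
  params <- list(n_abstracts = as.integer(n_abstracts),
                 intercept_log_risk = intercept_log_risk, log_rr = log_rr,
                 target_publication_rate = target_publication_rate,
                 p_first_coi = p_first_coi, p_sig_reported = p_sig_reported,
                 p_sig_given_reported = p_sig_given_reported,
                 p_funding = p_funding,
                 coi_flag_marginals = coi_flag_marginals,
                 rule_mix = rule_mix, time_meanlog = time_meanlog,
                 time_sdlog = time_sdlog, time_range = time_range,
                 discordance_mix = discordance_mix,
                 p_same_domain = p_same_domain,
                 p_comparable_given_same_domain =
                   p_comparable_given_same_domain,
                 followup_horizons = followup_horizons,
                 year_weights = year_weights / sum(year_weights),
                 seed = as.integer(seed))
  class(params) <- "cohort_params"
  params
}

#' Publication proportion implied by generator parameters
#'
#' Closed-form mean of the log-linear publication model over the
#' independent covariate distribution; used to check the generator against
#' its own stated world.
#'
#' @param params a [cohort_params()].
#' @return implied mean publication probability.
#' @export
implied_publication_rate <- function(params) {
  prev <- c(sig_reported = params$p_sig_reported,
            first_coi = params$p_first_coi,
            funding_none = unname(params$p_funding["none"]))
  exp(params$intercept_log_risk) *
    prod(1 - prev[names(params$log_rr)] +
           prev[names(params$log_rr)] * exp(params$log_rr))
}

.DOMAINS <- c("intraocular pressure", "visual acuity", "contrast sensitivity",
              "macular thickness", "corneal endothelial cell density",
              "tear film breakup time", "retinal nerve fiber layer thickness",
              "visual field mean deviation")

# A main-outcome report realizing a given significance class. Estimates are
# ratio measures rounded to printed precision; the not_reported class mixes
# estimate-only reports with bare significance claims.
.make_outcome <- function(sig_class, order, domain, time_value = 6,
                          is_primary = FALSE, in_title = FALSE,
                          claim_prob = 0.2) {
  cmp <- switch(sig_class,
    significant = list(effect_estimate(
      "ratio_measure", value = round(exp(stats::runif(1, log(1.2), log(2.2))), 2),
      p_value = round(stats::runif(1, 0.001, 0.045), 3))),
    not_significant = list(effect_estimate(
      "ratio_measure", value = round(exp(stats::runif(1, log(0.85), log(1.25))), 2),
      p_value = round(stats::runif(1, 0.07, 0.9), 2))),
    not_reported = if (stats::runif(1) < claim_prob) list()
    else list(effect_estimate(
      "ratio_measure",
      value = round(exp(stats::runif(1, log(0.9), log(1.8))), 2))))
  outcome_report(domain = domain, time_value = time_value,
                 time_unit = "months", is_primary = is_primary,
                 in_title_or_objective = in_title, results_order = order,
                 comparisons = cmp,
                 claims_significance_without_data = length(cmp) == 0L)
}

# Publication main outcome realizing a discordance category relative to the
# abstract's main outcome. Only called when the abstract's main outcome
# classifies as significant or not significant.
.make_publication_outcome <- function(abs_main, category) {
  domain <- abs_main$domain
  tv <- abs_main$time_value
  mk <- function(cmp) outcome_report(domain = domain, time_value = tv,
                                     time_unit = abs_main$time_unit,
                                     results_order = 1L,
                                     comparisons = list(cmp))
  a_cmp <- if (length(abs_main$comparisons)) abs_main$comparisons[[1]] else NULL
  sig_a <- classify_outcome(abs_main)
  if (category == "exact") return(mk(a_cmp))
  if (category == "qualitative") {
    # Flip significance status, same direction of effect.
    if (sig_a == "significant")
      return(mk(effect_estimate("ratio_measure",
                                value = max(round(a_cmp$value * 0.9, 2), 1.01),
                                p_value = 0.4)))
    return(mk(effect_estimate("ratio_measure",
                              value = round(max(a_cmp$value, 1.05) * 1.3, 2),
                              p_value = 0.01)))
  }
  if (category == "unclear") {
    # Comparable only through p-values.
    p_a <- a_cmp$p_value
    p_pub <- if (p_a < 0.05) {
      if (abs(p_a - 0.03) > 0.005) 0.03 else 0.01
    } else {
      if (abs(p_a - 0.3) > 0.05) 0.3 else 0.5
    }
    return(mk(effect_estimate("ratio_measure", p_value = p_pub)))
  }
  # Banded quantitative categories: publication value on the same side of
  # the null, abstract value = publication value scaled by an interior
  # percent difference, significance status preserved. Both values are
  # drawn at full 2-decimal precision (rejection loop) so the
  # printed-precision equality rule cannot collapse the pair to exact
  # agreement, and the realized percent difference is re-checked against
  # the interior of its band after rounding.
  band <- switch(category, lt10 = c(1.5, 9.5), `10to20` = c(10.5, 19.5),
                 gt20 = c(20.5, 80))
  repeat {
    pd <- stats::runif(1, band[1] + 0.5, band[2] - 0.5)
    w <- round(stats::runif(1, 1.20, 1.90), 2)
    a_val <- round(w * (1 + pd / 100), 2)
    pd_act <- (a_val - w) / w * 100
    if (.decimals_needed(w) == 2L && .decimals_needed(a_val) == 2L &&
        pd_act > band[1] && pd_act < band[2]) break
  }
  p_pair <- if (sig_a == "significant") c(0.01, 0.02) else c(0.2, 0.3)
  abs_cmp <- effect_estimate("ratio_measure", value = a_val,
                             p_value = p_pair[1])
  pub_cmp <- effect_estimate("ratio_measure", value = w,
                             p_value = p_pair[2])
  list(abstract_main = outcome_report(domain = domain, time_value = tv,
                                      time_unit = abs_main$time_unit,
                                      is_primary = abs_main$is_primary,
                                      in_title_or_objective =
                                        abs_main$in_title_or_objective,
                                      results_order = abs_main$results_order,
                                      comparisons = list(abs_cmp)),
       publication_main = mk(pub_cmp))
}

.draw_coi_profile <- function(p_any, flag_marginals, disclosure) {
  if (stats::runif(1) >= p_any)
    return(coi_profile(disclosure_level = disclosure))
  cond <- pmin(flag_marginals / p_any, 0.95)
  repeat {
    draws <- stats::runif(length(cond)) < cond
    if (any(draws)) break
  }
  do.call(coi_profile, c(as.list(draws), list(disclosure_level = disclosure)))
}

#' Generate a synthetic cohort
#'
#' Draws a cohort of abstract/publication pairs with independent exposures
#' at the stated marginal prevalences, publication indicators from the
#' log-linear risk model, truncated log-normal publication times, and, for
#' published pairs that are comparable, a publication main outcome realizing
#' a category drawn from the discordance mixture. Every drawn label is
#' recoverable by the corresponding classifier (closed loop with the
#' pipeline).
#'
#' @param params a [cohort_params()].
#' @param seed integer seed (default `params$seed`).
#' @return list of [pair_record()]s.
#' @export
generate_cohort <- function(params = cohort_params(), seed = params$seed) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(seed)
  years <- as.integer(names(params$followup_horizons))
  n <- params$n_abstracts
  out <- vector("list", n)
  for (i in seq_len(n)) {
    year <- sample(years, 1, prob = params$year_weights[as.character(years)])
    per_author <- year != 2001L
    disclosure <- if (per_author) "per_author" else "team_aggregate"
    n_authors <- sample(1:7, 1)
    first <- .draw_coi_profile(params$p_first_coi,
                               params$coi_flag_marginals, disclosure)
    others <- replicate(max(n_authors - 1L, 0L),
                        .draw_coi_profile(0.1, params$coi_flag_marginals,
                                          disclosure),
                        simplify = FALSE)
    authors <- c(list(first), others)
    names(authors) <- sprintf("a%d_%02d", i, seq_along(authors))

    funding_cat <- sample(names(params$p_funding), 1,
                          prob = params$p_funding)
    funding <- switch(funding_cat,
                      not_reported = "not_reported", none = "none",
                      funded = unique(sample(c("industry", "government",
                                               "other"),
                                             sample(1:2, 1), replace = TRUE)))

    reported <- stats::runif(1) < params$p_sig_reported
    sig_class <- if (!reported) "not_reported"
    else if (stats::runif(1) < params$p_sig_given_reported) "significant"
    else "not_significant"

    rule <- sample(c(1L, 3L, 4L), 1, prob = params$rule_mix)
    n_outcomes <- sample(1:3, 1)
    domains <- sample(.DOMAINS, n_outcomes)
    main <- .make_outcome(sig_class, order = 1L, domain = domains[1],
                          time_value = sample(c(3, 6, 12, 24), 1),
                          is_primary = rule == 1L,
                          in_title = rule == 3L)
    extras <- if (n_outcomes > 1L) {
      lapply(2:n_outcomes, function(j)
        .make_outcome(sample(c("significant", "not_significant",
                               "not_reported"), 1,
                             prob = c(0.25, 0.25, 0.5)),
                      order = j, domain = domains[j],
                      time_value = 6))
    } else list()
    outcomes <- c(list(main), extras)

    x <- c(sig_reported = as.numeric(reported),
           first_coi = as.numeric(has_any_coi(first)),
           funding_none = as.numeric(identical(funding, "none")))
    log_p <- params$intercept_log_risk +
      sum(params$log_rr * x[names(params$log_rr)])
    published <- stats::runif(1) < exp(log_p)

    publication <- NULL
    if (published) {
      months <- round(stats::rlnorm(1, params$time_meanlog,
                                    params$time_sdlog))
      months <- min(max(months, params$time_range[1]), params$time_range[2])
      comparable <- sig_class != "not_reported" &&
        stats::runif(1) < params$p_same_domain &&
        stats::runif(1) < params$p_comparable_given_same_domain
      if (comparable) {
        category <- sample(names(params$discordance_mix), 1,
                           prob = params$discordance_mix)
        built <- .make_publication_outcome(main, category)
        if (is.list(built) && !inherits(built, "outcome_report")) {
          outcomes[[1]] <- built$abstract_main
          pub_main <- built$publication_main
        } else pub_main <- built
      } else {
        # Different domain (or an unreported abstract): not comparable.
        pub_main <- .make_outcome("significant", order = 1L,
                                  domain = setdiff(.DOMAINS, domains)[1],
                                  time_value = 6)
      }
      publication <- publication_record(
        publication_id = sprintf("p%04d", i),
        months_after_presentation = months,
        outcomes = list(pub_main))
    }
    abstract <- abstract_record(
      abstract_id = sprintf("abs%04d", i), conference_year = year,
      presentation = sample(c("poster", "oral"), 1, prob = c(0.815, 0.185)),
      funding = funding,
      centers = sample(c("not_reported", "single", "multi"), 1,
                       prob = c(0.704, 0.09, 0.206)),
      authors = authors, outcomes = outcomes)
    out[[i]] <- pair_record(abstract, publication,
                            params$followup_horizons[[as.character(year)]])
  }
  out
}

#' Self-verifying fixture of comparable abstract/publication pairs
#'
#' Builds one pair per requested discordance category and verifies that
#' [classify_pair()] recovers the intended category (an internal error
#' otherwise), so the fixture cannot drift from the classifier.
#'
#' @param composition named or positional counts over
#'   `exact`, `qualitative`, `lt10`, `10to20`, `gt20`, `unclear`
#'   (default the published 86-pair mix 39/7/14/5/14/7).
#' @param seed integer seed.
#' @return list of comparable [pair_record()]s.
#' @export
generate_pair_fixture <- function(composition = c(exact = 39,
                                                  qualitative = 7,
                                                  lt10 = 14, `10to20` = 5,
                                                  gt20 = 14, unclear = 7),
                                  seed = 1L) {
  cat_levels <- c("exact", "qualitative", "lt10", "10to20", "gt20",
                  "unclear")
  if (is.null(names(composition))) names(composition) <- cat_levels
  stopifnot(all(names(composition) %in% cat_levels), all(composition >= 0))
  target <- c(exact = "exact_agreement", qualitative = "qualitative",
              lt10 = "quant_lt10", `10to20` = "quant_10to20",
              gt20 = "quant_gt20", unclear = "quant_unclear")
  set.seed(seed)
  labels <- rep(names(composition), composition)
  out <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    category <- labels[i]
    sig_class <- sample(c("significant", "not_significant"), 1)
    domain <- sample(.DOMAINS, 1)
    tv <- sample(c(3, 6, 12, 24), 1)
    if (category == "unclear") {
      p_a <- if (sig_class == "significant") 0.01 else 0.2
      abs_main <- outcome_report(domain, tv, results_order = 1L,
                                 comparisons = list(
                                   effect_estimate("ratio_measure",
                                                   p_value = p_a)))
    } else {
      abs_main <- .make_outcome(sig_class, 1L, domain, tv)
    }
    built <- .make_publication_outcome(abs_main, category)
    if (is.list(built) && !inherits(built, "outcome_report")) {
      pub_main <- built$publication_main
      abs_main <- built$abstract_main
    } else pub_main <- built
    got <- classify_pair(abs_main, pub_main)$category
    if (got != target[[category]])
      stop("fixture self-verification failed: built ", category,
           " but classified ", got)
    abstract <- abstract_record(sprintf("fix%03d", i), 2002L,
                                authors = list(a1 = coi_profile()),
                                outcomes = list(abs_main))
    publication <- publication_record(sprintf("fixp%03d", i),
                                      months_after_presentation = 12L +
                                        (i %% 24L),
                                      outcomes = list(pub_main))
    out[[i]] <- pair_record(abstract, publication, 134L)
  }
  out
}

# Deterministic time-to-publication spread for the margins fixture:
# log-normal quantiles rounded to whole months and clamped to [1, 90].
.fixture_months <- function(n, meanlog = log(18),
                            sdlog = log(3) / (2 * stats::qnorm(0.75))) {
  q <- stats::qlnorm((seq_len(n) - 0.5) / n, meanlog, sdlog)
  pmin(pmax(round(q), 1), 90)
}

#' Deterministic cohort reproducing the published 2x2 margins
#'
#' Builds a 513-abstract cohort whose tallies reproduce, simultaneously,
#' the published margins for: main-outcome significance reported
#' (123/228 vs 107/285), any-outcome significance reported (135/249 vs
#' 95/264), the significance strata among reporters (64/117 significant,
#' 59/111 not), first-author COI among the 400 individually disclosed
#' abstracts (67/132 vs 104/268), first-author financial support
#' (44/75 vs 127/325), first-author gifts (21/36 vs 150/364), and no
#' funding (41/114 vs 189/399). Joint counts the margins do not constrain
#' are completed deterministically. The construction is verified against
#' [build_table()] before returning (an error on any mismatch).
#'
#' @return list of 513 [pair_record()]s (230 published).
#' @export
margins_fixture <- function() {
  n_pub <- 230L; n_unpub <- 283L
  months <- .fixture_months(n_pub)

  # Per-record attribute schedule. Published records first (index 1..230),
  # then unpublished (231..513). Within each block, index ranges assign:
  # cohort year (2001 first, then 2002-2004 cycling), significance class,
  # the extra any-outcome reporters, funding, and first-author COI flags
  # (only within the 2002-2004 block).
  schedule <- function(n, n_2001, sig, extra_any, fund_none, fund_yes,
                       coi_any, coi_fin, coi_gift) {
    year <- c(rep(2001L, n_2001),
              rep(c(2002L, 2003L, 2004L), length.out = n - n_2001))
    # Interleave the significance classes across indices (deterministic
    # golden-ratio permutation) so their joint with year and COI, which
    # the margins leave free, keeps every interaction-model cell
    # populated. A permutation cannot change any marginal count.
    perm <- order((seq_len(n) * (sqrt(5) - 1) / 2) %% 1)
    cls <- rep(c("significant", "not_significant", "not_reported"),
               sig)[perm]
    extra <- logical(n)
    extra[which(cls == "not_reported")[seq_len(extra_any)]] <- TRUE
    funding <- rep("not_reported", n)
    funding[seq_len(fund_none)] <- "none"
    funding[(fund_none + 1):(fund_none + fund_yes)] <- "funded"
    # COI positions live in the 2002-2004 block (indices > n_2001). The
    # margins do not constrain the joint of COI with significance class,
    # so spread the exposed records evenly across the block: every
    # exposure-by-stratum cell of the interaction model stays populated.
    base <- n_2001
    block <- n - base
    pos <- base + floor((seq_len(coi_any) - 1) * block / coi_any) + 1L
    coi <- rep(NA_character_, n)
    coi[pos[seq_len(coi_fin)]] <- "financial_support"
    coi[pos[coi_fin + seq_len(coi_gift)]] <- "received_gifts"
    n_other <- coi_any - coi_fin - coi_gift
    if (n_other > 0)
      coi[pos[coi_fin + coi_gift + seq_len(n_other)]] <-
        "consultant_to_business"
    data.frame(year = year, cls = cls, extra_any = extra, funding = funding,
               coi = coi, stringsAsFactors = FALSE)
  }
  pub <- schedule(n_pub, n_2001 = 59L, sig = c(64L, 59L, 107L),
                  extra_any = 12L, fund_none = 41L, fund_yes = 85L,
                  coi_any = 67L, coi_fin = 44L, coi_gift = 21L)
  unpub <- schedule(n_unpub, n_2001 = 54L, sig = c(53L, 52L, 178L),
                    extra_any = 9L, fund_none = 73L, fund_yes = 73L,
                    coi_any = 65L, coi_fin = 31L, coi_gift = 15L)
  pub$published <- TRUE; unpub$published <- FALSE
  pub$months <- months; unpub$months <- NA_integer_
  tab <- rbind(pub, unpub)

  horizons <- c(`2001` = 146L, `2002` = 134L, `2003` = 122L, `2004` = 110L)
  build_one <- function(i) {
    row <- tab[i, ]
    main_cmp <- switch(row$cls,
      significant = list(effect_estimate("ratio_measure", 1.50,
                                         p_value = 0.01)),
      not_significant = list(effect_estimate("ratio_measure", 1.05,
                                             p_value = 0.40)),
      not_reported = list(effect_estimate("ratio_measure", 1.20)))
    outcomes <- list(outcome_report("intraocular pressure", 6,
                                    results_order = 1L,
                                    comparisons = main_cmp))
    if (row$extra_any)
      outcomes <- c(outcomes, list(outcome_report(
        "visual acuity", 6, results_order = 2L,
        comparisons = list(effect_estimate("ratio_measure", 1.10,
                                           p_value = 0.30)))))
    flags <- if (is.na(row$coi)) list() else stats::setNames(list(TRUE), row$coi)
    disclosure <- if (row$year == 2001L) "team_aggregate" else "per_author"
    first <- do.call(coi_profile, c(flags,
                                    list(disclosure_level = disclosure)))
    funding <- switch(row$funding, none = "none",
                      not_reported = "not_reported", funded = "industry")
    abstract <- abstract_record(sprintf("m%03d", i), row$year,
                                funding = funding,
                                authors = list(a1 = first,
                                               a2 = coi_profile(
                                                 disclosure_level = disclosure)),
                                outcomes = outcomes)
    publication <- if (row$published) {
      publication_record(sprintf("mp%03d", i),
                         months_after_presentation = row$months,
                         outcomes = outcomes[1])
    } else NULL
    pair_record(abstract, publication, horizons[[as.character(row$year)]])
  }
  cohort <- lapply(seq_len(nrow(tab)), build_one)

  # Internal consistency check against the published margins.
  expect_tab <- function(tab, a, n1, c, n0) {
    if (!(tab$a == a && tab$n1 == n1 && tab$c == c && tab$n0 == n0))
      stop("margins fixture inconsistent: got (", tab$a, ",", tab$n1, ",",
           tab$c, ",", tab$n0, "), wanted (", a, ",", n1, ",", c, ",", n0,
           ")")
  }
  expect_tab(build_table(cohort, exposure_sig_reported()),
             123, 228, 107, 285)
  expect_tab(build_table(cohort, exposure_any_sig_reported()),
             135, 249, 95, 264)
  expect_tab(build_table(cohort, exposure_significant()), 64, 117, 59, 111)
  expect_tab(build_table(cohort, exposure_coi("first", "any")),
             67, 132, 104, 268)
  expect_tab(build_table(cohort, exposure_coi("first", "financial_support")),
             44, 75, 127, 325)
  expect_tab(build_table(cohort, exposure_coi("first", "received_gifts")),
             21, 36, 150, 364)
  expect_tab(build_table(cohort, exposure_funding_none()),
             41, 114, 189, 399)
  cohort
}
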