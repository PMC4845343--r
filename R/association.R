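#' 2x2 exposure-by-publication table
#'
#' @param a exposed and published count.
#' @param n1 exposed total.
#' @param c unexposed and published count.
#' @param n0 unexposed total.
#' @return object of class `two_by_two`.
#' @export
two_by_two <- function(a, n1, c, n0) {
  stopifnot(.is_count(a), .is_count(n1), .is_count(c), .is_count(n0))
  if (a > n1 || c > n0) stop("cell count exceeds its group total")
  if (n1 + n0 == 0) stop("empty table")
  structure(list(a = as.integer(a), n1 = as.integer(n1),
                 c = as.integer(c), n0 = as.integer(n0)),
            class = "two_by_two")
}

#' Tally a 2x2 exposure-by-publication table from a cohort
#'
#' `exposure` is a predicate `function(pair) -> TRUE/FALSE/NA`; records with
#' `NA` exposure (e.g. per-author COI before it was collected) are excluded
#' from the table. The comparator is either the complement of the exposed
#' set within the analyzable cohort, or an explicit reference predicate
#' (e.g. single-center as the referent for multicenter).
#'
#' @param cohort list of [pair_record()]s.
#' @param exposure predicate function of a pair.
#' @param comparator `"complement"` or `"explicit_reference"`.
#' @param reference predicate for the referent group when
#'   `comparator = "explicit_reference"`.
#' @return a [two_by_two()].
#' @export
build_table <- function(cohort, exposure,
                        comparator = c("complement", "explicit_reference"),
                        reference = NULL) {
  comparator <- match.arg(comparator)
  exp_flags <- vapply(cohort, function(p) as.logical(exposure(p)), logical(1))
  pub_flags <- vapply(cohort, is_published, logical(1))
  exposed <- which(!is.na(exp_flags) & exp_flags)
  unexposed <- if (comparator == "complement") {
    which(!is.na(exp_flags) & !exp_flags)
  } else {
    if (is.null(reference))
      stop("explicit_reference comparator needs a reference predicate")
    ref_flags <- vapply(cohort, function(p) as.logical(reference(p)),
                        logical(1))
    if (any(!is.na(exp_flags) & exp_flags & !is.na(ref_flags) & ref_flags))
      stop("exposure and reference groups overlap")
    which(!is.na(ref_flags) & ref_flags)
  }
  if (length(exposed) == 0L) stop("empty exposed group")
  if (length(unexposed) == 0L) stop("empty comparator group")
  two_by_two(a = sum(pub_flags[exposed]), n1 = length(exposed),
             c = sum(pub_flags[unexposed]), n0 = length(unexposed))
}

.rr_estimate <- function(rr, ci_low, ci_high, log_se, n_used) {
  stopifnot(ci_low <= rr + 1e-12, rr <= ci_high + 1e-12, log_se >= 0)
  structure(list(rr = rr, ci_low = ci_low, ci_high = ci_high,
                 log_se = log_se, n_used = as.integer(n_used)),
            class = "rr_estimate")
}

#' @export
print.rr_estimate <- function(x, ...) {
  cat(sprintf("RR %s (95%% CI %s to %s), n = %d\n", fmt_rr(x$rr),
              fmt_rr(x$ci_low), fmt_rr(x$ci_high), x$n_used))
  invisible(x)
}

#' Crude risk ratio with Katz confidence interval
#'
#' `RR = (a/n1) / (c/n0)` with the Katz log-scale standard error
#' `sqrt(1/a - 1/n1 + 1/c - 1/n0)` and a Wald interval on the log scale.
#' Zero numerator cells are an error (no continuity correction; such rows
#' are reported as inestimable).
#'
#' @param table a [two_by_two()].
#' @param conf_level confidence level (default 0.95).
#' @return an `rr_estimate` with fields `rr`, `ci_low`, `ci_high`,
#'   `log_se`, `n_used`.
#' @export
#' @examples
#' crude_rr(two_by_two(123, 228, 107, 285))  # RR 1.44 (1.19 to 1.74)
crude_rr <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "two_by_two"))
  if (table$a == 0 || table$c == 0)
    stop("zero numerator cell: risk ratio inestimable without correction")
  rr <- (table$a / table$n1) / (table$c / table$n0)
  log_se <- sqrt(1 / table$a - 1 / table$n1 + 1 / table$c - 1 / table$n0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  .rr_estimate(rr, exp(log(rr) - z * log_se), exp(log(rr) + z * log_se),
               log_se, table$n1 + table$n0)
}

#' Log-binomial regression by iteratively reweighted least squares
#'
#' Maximum-likelihood fit of a binomial model with logarithmic link, so that
#' exponentiated coefficients are risk ratios. Fisher-scoring IRLS with
#' step-halving keeps fitted probabilities inside (0, 1); convergence is
#' declared when the largest coefficient change falls below `tol`.
#' Non-convergence, a boundary fit, or a singular information matrix is an
#' explicit error (no silent fallback).
#'
#' @param responses 0/1 vector.
#' @param design numeric matrix (or data.frame) of covariates, without
#'   intercept; an intercept column is added internally.
#' @param tol convergence tolerance on the max absolute coefficient change.
#' @param max_iter iteration cap.
#' @param conf_level confidence level for the per-covariate RR intervals.
#' @return list of class `log_binomial_fit` with `coefficients`, `vcov`,
#'   `fitted`, `deviance`, `iterations`, `converged`, and `rr` (a named list
#'   of `rr_estimate`s, one per covariate column).
#' @export
fit_log_binomial <- function(responses, design, tol = 1e-8, max_iter = 100L,
                             conf_level = 0.95) {
  y <- as.numeric(responses)
  if (!all(y %in% c(0, 1))) stop("responses must be binary 0/1")
  X <- as.matrix(design)
  if (ncol(X) > 0L && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  X <- cbind(`(intercept)` = 1, X)
  if (qr(X)$rank < ncol(X)) stop("design matrix is not full rank")
  n <- length(y)
  stopifnot(nrow(X) == n)

  loglik <- function(mu) sum(y * log(mu) + (1 - y) * log1p(-mu))
  # Start at the intercept-only MLE; log(mean) keeps eta < 0.
  beta <- c(log(max(mean(y), 1 / (2 * n))), rep(0, ncol(X) - 1L))
  eta <- drop(X %*% beta)
  mu <- exp(eta)
  mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
  ll_old <- loglik(mu)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    w <- mu / (1 - mu)                 # Fisher weights for the log link
    z <- eta + (y - mu) / mu           # working response
    fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients))
      stop("log-binomial IRLS failed: singular weighted least-squares step")
    beta_new <- fit$coefficients
    # Step-halve until fitted probabilities are admissible and the
    # likelihood does not decrease.
    step <- beta_new - beta
    halvings <- 0L
    repeat {
      cand <- beta + step
      eta_c <- drop(X %*% cand)
      mu_c <- exp(eta_c)
      ok <- all(mu_c < 1 - 1e-10) && all(mu_c > 0)
      if (ok && loglik(mu_c) >= ll_old - 1e-12) break
      step <- step / 2
      halvings <- halvings + 1L
      if (halvings > 50L)
        stop("log-binomial IRLS failed: step-halving exhausted ",
             "(fitted probability at the boundary); max fitted p = ",
             signif(max(mu), 4))
    }
    delta <- max(abs(cand - beta))
    beta <- cand; eta <- eta_c; mu <- mu_c; ll_old <- loglik(mu)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("log-binomial IRLS did not converge in ", max_iter,
         " iterations (last max coefficient change ", signif(delta, 3), ")")
  if (any(mu > 1 - 1e-6))
    stop("log-binomial fit reached the boundary: fitted probability ",
         "of 1 for ", sum(mu > 1 - 1e-6), " observation(s)")
  w <- mu / (1 - mu)
  info <- crossprod(X * sqrt(w))
  vcov <- tryCatch(solve(info), error = function(e)
    stop("log-binomial fit: singular information matrix"))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  dev <- -2 * (ll_old - sum(stats::dbinom(y, 1, pmax(pmin(y, 1 - 1e-12), 1e-12),
                                          log = TRUE)))
  z_crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  rr <- lapply(setdiff(colnames(X), "(intercept)"), function(nm) {
    se <- sqrt(vcov[nm, nm])
    .rr_estimate(exp(beta[[nm]]), exp(beta[[nm]] - z_crit * se),
                 exp(beta[[nm]] + z_crit * se), se, n)
  })
  names(rr) <- setdiff(colnames(X), "(intercept)")
  structure(list(coefficients = beta, vcov = vcov, fitted = mu,
                 deviance = dev, iterations = iter, converged = converged,
                 rr = rr),
            class = "log_binomial_fit")
}

#' Interaction model: COI-by-significance-stratum risk ratios
#'
#' Fits a log-binomial model of publication on an exposure (typically a COI
#' indicator) with interaction terms for (1) whether statistical
#' significance of the abstract's main outcome was reported and (2) whether
#' the main outcome was statistically significant. Exponentiated coefficient
#' sums give the exposure RR within each of the three significance strata
#' (`not_significant`, `significant`, `not_reported`), and a joint Wald
#' chi-square test on the two interaction coefficients (2 df) assesses the
#' overall significance of the interaction.
#'
#' @param cohort list of [pair_record()]s.
#' @param exposure predicate `function(pair) -> TRUE/FALSE/NA`; `NA` records
#'   are excluded.
#' @param alpha significance level used to classify the main outcome.
#' @param conf_level confidence level for stratum RR intervals.
#' @return list of class `interaction_fit` with `stratum_rr` (named list of
#'   `rr_estimate`s), `joint_test_statistic`, `joint_test_df`,
#'   `joint_test_p`, and the underlying `fit`.
#' @export
fit_interaction_model <- function(cohort, exposure, alpha = 0.05,
                                  conf_level = 0.95) {
  exp_flags <- vapply(cohort, function(p) as.logical(exposure(p)), logical(1))
  keep <- which(!is.na(exp_flags))
  if (length(keep) == 0L) stop("no analyzable records for this exposure")
  sub <- cohort[keep]
  x <- as.numeric(exp_flags[keep])
  y <- as.numeric(vapply(sub, is_published, logical(1)))
  cls <- vapply(sub, abstract_main_significance, character(1), alpha = alpha)
  reported <- as.numeric(cls != "not_reported")
  significant <- as.numeric(cls == "significant")

  strata <- c("not_significant", "significant", "not_reported")
  for (s in strata) for (e in 0:1) {
    if (sum(cls == s & x == e) == 0L)
      stop("empty stratum cell: ", s, ", exposure = ", e)
  }

  design <- cbind(exposure = x, reported = reported,
                  significant = significant,
                  `exposure:reported` = x * reported,
                  `exposure:significant` = x * significant)
  fit <- fit_log_binomial(y, design, conf_level = conf_level)
  b <- fit$coefficients
  V <- fit$vcov
  z_crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  # Contrast vectors picking out the exposure log-RR within each stratum.
  contrast <- function(nms) {
    v <- stats::setNames(numeric(length(b)), names(b))
    v[nms] <- 1
    v
  }
  cons <- list(
    not_significant = contrast(c("exposure", "exposure:reported")),
    significant = contrast(c("exposure", "exposure:reported",
                             "exposure:significant")),
    not_reported = contrast("exposure"))
  stratum_rr <- lapply(cons, function(v) {
    est <- sum(v * b)
    se <- sqrt(drop(t(v) %*% V %*% v))
    .rr_estimate(exp(est), exp(est - z_crit * se), exp(est + z_crit * se),
                 se, length(y))
  })
  inter <- c("exposure:reported", "exposure:significant")
  bi <- b[inter]
  Vi <- V[inter, inter]
  stat <- drop(t(bi) %*% solve(Vi) %*% bi)
  p <- stats::pchisq(stat, df = length(inter), lower.tail = FALSE)
  structure(list(stratum_rr = stratum_rr, joint_test_statistic = stat,
                 joint_test_df = length(inter), joint_test_p = p,
                 fit = fit),
            class = "interaction_fit")
}

#' Standard exposure predicates
#'
#' Factories for the exposure definitions used throughout the analysis.
#' Each returns a `function(pair) -> TRUE/FALSE/NA`; `NA` marks records
#' excluded from that analysis (e.g. per-author COI is only available from
#' cohort year 2002 onward, when authors disclosed individually).
#'
#' @param alpha significance level for significance-based exposures.
#' @param role `"first"`, `"last"`, or `"any"` author.
#' @param flag one of the six COI categories (see `COI_FLAGS`) or `"any"`.
#' @name exposures
NULL

#' @rdname exposures
#' @export
exposure_sig_reported <- function(alpha = 0.05) {
  function(pair) abstract_main_significance(pair, alpha) != "not_reported"
}

#' @rdname exposures
#' @export
exposure_any_sig_reported <- function(alpha = 0.05) {
  function(pair) classify_any_outcome(pair$abstract, alpha) != "not_reported"
}

#' @rdname exposures
#' @export
exposure_significant <- function(alpha = 0.05) {
  function(pair) {
    cls <- abstract_main_significance(pair, alpha)
    if (cls == "not_reported") NA else cls == "significant"
  }
}

#' @rdname exposures
#' @export
exposure_coi <- function(role = c("first", "last", "any"), flag = "any") {
  role <- match.arg(role)
  if (!flag %in% c("any", COI_FLAGS)) stop("unknown COI flag: ", flag)
  coi_hit <- function(profile) {
    if (flag == "any") has_any_coi(profile) else isTRUE(profile[[flag]])
  }
  function(pair) {
    authors <- pair$abstract$authors
    levels <- vapply(authors, function(a) a$disclosure_level, character(1))
    if (role == "any") {
      # Team-aggregate disclosure (2001) still informs the any-author view.
      if (all(levels == "not_reported")) return(NA)
      return(any(vapply(authors, coi_hit, logical(1))))
    }
    profile <- if (role == "first") authors[[1L]]
    else authors[[length(authors)]]
    if (profile$disclosure_level != "per_author") return(NA)
    coi_hit(profile)
  }
}

#' @rdname exposures
#' @export
exposure_funding_none <- function() {
  function(pair) identical(pair$abstract$funding, "none")
}

#' @rdname exposures
#' @export
exposure_funding_reported <- function() {
  function(pair) !identical(pair$abstract$funding, "not_reported")
}
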