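# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so imputation draws never perturb other
# simulations.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Impute unreported main-outcome significance
#'
#' Relabels the abstracts whose main-outcome significance is `not_reported`
#' under a hypothetical assumption: a fraction of them (selected uniformly
#' at random without replacement, seeded) is assumed `significant` and the
#' remainder `not_significant`. Abstracts that reported significance are
#' untouched. The number relabeled significant is `round(fraction * m)`
#' (half away from zero) of the `m` unreported abstracts, so fractions 0
#' and 1 are deterministic regardless of seed.
#'
#' @param cohort list of [pair_record()]s.
#' @param fraction assumed proportion significant among unreported, in
#'   `[0, 1]`.
#' @param seed integer seed for the uniform draw.
#' @param alpha significance level for the observed classification.
#' @return data.frame with one row per abstract: `abstract_id`,
#'   `published`, `class_observed`, `class_imputed` (never
#'   `not_reported`).
#' @export
impute_significance <- function(cohort, fraction, seed = 1L, alpha = 0.05) {
  stopifnot(is.numeric(fraction), length(fraction) == 1L,
            fraction >= 0, fraction <= 1)
  observed <- vapply(cohort, abstract_main_significance, character(1),
                     alpha = alpha)
  published <- vapply(cohort, is_published, logical(1))
  ids <- vapply(cohort, function(p) p$abstract$abstract_id, character(1))
  imputed <- observed
  nr <- which(observed == "not_reported")
  m <- length(nr)
  if (m > 0L) {
    k <- floor(fraction * m + 0.5)      # round half up
    chosen <- if (k == 0L) integer(0)
    else if (k == m) nr
    else .with_seed(seed, nr[sample.int(m, k)])
    imputed[nr] <- "not_significant"
    imputed[chosen] <- "significant"
  }
  data.frame(abstract_id = ids, published = published,
             class_observed = observed, class_imputed = imputed,
             stringsAsFactors = FALSE)
}

#' Assumption-based sensitivity analysis of significance and publication
#'
#' For each assumed fraction of unreported results that are in fact
#' statistically significant, imputes significance with
#' [impute_significance()] and estimates the crude risk ratio of
#' publication for significant versus not-significant main outcomes.
#' Assumptions with fraction 0 or 1 are deterministic; intermediate
#' fractions are single seeded draws (one independent draw per assumption).
#'
#' @param cohort list of [pair_record()]s.
#' @param grid assumed fractions (default the five-assumption grid
#'   0, 0.25, 0.5, 0.75, 1).
#' @param seed base seed; assumption i uses `seed + i`.
#' @param alpha significance level.
#' @return data.frame with one row per assumption: `fraction`, `rr`,
#'   `ci_low`, `ci_high`, the post-imputation table cells, and
#'   `deterministic`.
#' @export
assumption_analysis <- function(cohort, grid = c(0, 0.25, 0.5, 0.75, 1),
                                seed = 1L, alpha = 0.05) {
  rows <- lapply(seq_along(grid), function(i) {
    f <- grid[i]
    imp <- impute_significance(cohort, f, seed = seed + i, alpha = alpha)
    sig <- imp$class_imputed == "significant"
    tab <- two_by_two(a = sum(imp$published[sig]), n1 = sum(sig),
                      c = sum(imp$published[!sig]), n0 = sum(!sig))
    if (tab$n1 == 0L || tab$n0 == 0L)
      stop("degenerate post-imputation table at fraction ", f)
    est <- crude_rr(tab)
    data.frame(fraction = f, rr = est$rr, ci_low = est$ci_low,
               ci_high = est$ci_high, a = tab$a, n1 = tab$n1, c = tab$c,
               n0 = tab$n0, deterministic = f %in% c(0, 1))
  })
  do.call(rbind, rows)
}

#' Across-seed distribution of an assumption's risk ratio
#'
#' Because a single random draw is not reproducible without the original
#' seed, stochastic assumptions are summarized by their across-seed
#' distribution.
#'
#' @param cohort list of [pair_record()]s.
#' @param fraction assumed fraction significant among unreported.
#' @param seeds integer vector of seeds (>= 200 recommended).
#' @param alpha significance level.
#' @return list with `rr` (vector over seeds), `mean`, `q2.5`, `q97.5`,
#'   `min`, `max`.
#' @export
assumption_distribution <- function(cohort, fraction, seeds = 1:200,
                                    alpha = 0.05) {
  rr <- vapply(seeds, function(s) {
    imp <- impute_significance(cohort, fraction, seed = s, alpha = alpha)
    sig <- imp$class_imputed == "significant"
    crude_rr(two_by_two(sum(imp$published[sig]), sum(sig),
                        sum(imp$published[!sig]), sum(!sig)))$rr
  }, numeric(1))
  q <- stats::quantile(rr, c(0.025, 0.975), names = FALSE)
  list(rr = rr, mean = mean(rr), q2.5 = q[1], q97.5 = q[2],
       min = min(rr), max = max(rr))
}
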