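test_that("crude_rr reproduces hand-checked tables", {
  est <- crude_rr(two_by_two(123, 228, 107, 285))
  expect_equal(round(est$rr, 2), 1.44)
  expect_equal(round(est$ci_low, 2), 1.19)
  expect_equal(round(est$ci_high, 2), 1.74)
  expect_equal(est$log_se, sqrt(1 / 123 - 1 / 228 + 1 / 107 - 1 / 285))

  est <- crude_rr(two_by_two(41, 114, 189, 399))
  expect_equal(round(est$rr, 2), 0.76)

  est <- crude_rr(two_by_two(10, 20, 10, 20))
  expect_equal(est$rr, 1)
  expect_lt(est$ci_low, 1)
  expect_gt(est$ci_high, 1)

  expect_error(crude_rr(two_by_two(0, 20, 10, 20)), "zero numerator")
  expect_error(two_by_two(25, 20, 10, 20), "exceeds")
})

test_that("swapping exposed and unexposed inverts the estimate", {
  est <- crude_rr(two_by_two(67, 132, 104, 268))
  inv <- crude_rr(two_by_two(104, 268, 67, 132))
  expect_equal(inv$rr, 1 / est$rr)
  expect_equal(inv$ci_low, 1 / est$ci_high)
  expect_equal(inv$ci_high, 1 / est$ci_low)
})

test_that("build_table tallies the margins fixture correctly", {
  cohort <- margins_fixture()
  tab <- build_table(cohort, exposure_sig_reported())
  expect_identical(unlist(tab[c("a", "n1", "c", "n0")], use.names = FALSE),
                   c(123L, 228L, 107L, 285L))
  tab <- build_table(cohort, exposure_coi("first", "any"))
  expect_identical(unlist(tab[c("a", "n1", "c", "n0")], use.names = FALSE),
                   c(67L, 132L, 104L, 268L))
  expect_error(build_table(cohort, function(p) TRUE), "empty comparator")
})

test_that("log-binomial fit matches the closed-form crude RR and glm", {
  tables <- list(c(67, 132, 104, 268), c(123, 228, 107, 285),
                 c(21, 36, 150, 364))
  for (tb in tables) {
    crude <- crude_rr(two_by_two(tb[1], tb[2], tb[3], tb[4]))
    x <- rep(c(1, 0), c(tb[2], tb[4]))
    y <- c(rep(1:0, c(tb[1], tb[2] - tb[1])),
           rep(1:0, c(tb[3], tb[4] - tb[3])))
    fit <- fit_log_binomial(y, cbind(exposed = x))
    expect_equal(fit$rr$exposed$rr, crude$rr, tolerance = 1e-6)
    expect_equal(fit$rr$exposed$log_se, crude$log_se, tolerance = 1e-4)
    # Independent oracle: base-R glm with a log link.
    g <- suppressWarnings(stats::glm(y ~ x, family = binomial("log"),
                                     start = c(log(mean(y)), 0)))
    expect_equal(unname(fit$coefficients), unname(stats::coef(g)),
                 tolerance = 1e-6)
  }
})

test_that("the intercept-only fit is the overall publication proportion", {
  y <- rep(1:0, c(30, 70))
  fit <- fit_log_binomial(y, matrix(numeric(0), nrow = 100, ncol = 0))
  expect_equal(exp(fit$coefficients[["(intercept)"]]), 0.3,
               tolerance = 1e-8)
})

test_that("single-covariate MLE matches a brute-force likelihood grid", {
  tab <- two_by_two(18, 40, 11, 35)
  crude <- crude_rr(tab)
  loglik <- function(p0, rr) {
    p1 <- p0 * rr
    if (p1 >= 1) return(-Inf)
    tab$a * log(p1) + (tab$n1 - tab$a) * log(1 - p1) +
      tab$c * log(p0) + (tab$n0 - tab$c) * log(1 - p0)
  }
  p0_grid <- seq(0.05, 0.95, by = 0.0025)
  rr_grid <- seq(0.2, 4, by = 0.0025)
  ll <- outer(p0_grid, rr_grid, Vectorize(loglik))
  best <- arrayInd(which.max(ll), dim(ll))
  expect_equal(rr_grid[best[2]], crude$rr, tolerance = 0.005)
  expect_equal(p0_grid[best[1]], tab$c / tab$n0, tolerance = 0.005)
})

test_that("degenerate fits fail loudly", {
  expect_error(fit_log_binomial(c(1, 0, 2), cbind(x = 1:3)), "binary")
  expect_error(fit_log_binomial(rep(1:0, 5),
                                cbind(a = rep(1, 10), b = rep(1, 10))),
               "full rank")
  # All exposed published: the MLE sits on the boundary p = 1.
  y <- c(rep(1, 20), rep(1:0, c(5, 15)))
  x <- rep(c(1, 0), c(20, 20))
  expect_error(fit_log_binomial(y, cbind(x = x)), "boundary|converge")
})

test_that("the saturated interaction model equals stratified crude RRs", {
  cohort <- margins_fixture()
  exposure <- exposure_coi("first", "any")
  fit <- fit_interaction_model(cohort, exposure)
  for (stratum in c("significant", "not_significant", "not_reported")) {
    sub <- Filter(function(p)
      abstract_main_significance(p) == stratum &&
        !is.na(exposure(p)), cohort)
    crude <- crude_rr(build_table(sub, exposure))
    expect_equal(fit$stratum_rr[[stratum]]$rr, crude$rr,
                 tolerance = 1e-5, label = stratum)
  }
  expect_gte(fit$joint_test_p, 0)
  expect_lte(fit$joint_test_p, 1)
})

test_that("a construction with no interaction gives a null joint statistic", {
  # Identical exposure RR (exactly 2) in all three strata; the saturated
  # fit then has interaction coefficients exactly 0.
  cells <- expand.grid(cls = c("significant", "not_significant",
                               "not_reported"),
                       coi = c(TRUE, FALSE), stringsAsFactors = FALSE)
  base <- c(significant = 0.2, not_significant = 0.25, not_reported = 0.3)
  cells$n <- 100L
  cells$n_published <- as.integer(round(
    100 * base[cells$cls] * ifelse(cells$coi, 2, 1)))
  cohort <- mk_cohort(cells)
  fit <- fit_interaction_model(cohort, exposure_coi("first", "any"))
  expect_equal(fit$joint_test_statistic, 0, tolerance = 1e-6)
  for (stratum in names(fit$stratum_rr))
    expect_equal(fit$stratum_rr[[stratum]]$rr, 2, tolerance = 1e-6)

  # An empty stratum cell is a loud error.
  cohort_missing <- Filter(function(p)
    !(abstract_main_significance(p) == "significant" &&
        isTRUE(exposure_coi("first", "any")(p))), cohort)
  expect_error(fit_interaction_model(cohort_missing,
                                     exposure_coi("first", "any")),
               "empty stratum cell")
})
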