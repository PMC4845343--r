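test_that("cohorts convert to survival records with the 1-month convention", {
  cohort <- list(mk_pair(months = 18L, id = "ev"),
                 mk_pair(published = FALSE, id = "cens"))
  recs <- to_survival_records(cohort)
  expect_equal(recs$time_months, c(18, 134))
  expect_equal(recs$event, c(TRUE, FALSE))
  # Publication at/before presentation is coded month 1 upstream; the
  # record type refuses anything below 1.
  expect_error(publication_record("p", 0L, list(mk_outcome(mk_ratio(1.2)))),
               ">= 1")
  expect_error(to_survival_records(list()), "empty")
})

test_that("km_estimate matches the hand product-limit computation", {
  recs <- data.frame(time_months = c(2, 5, 7),
                     event = c(TRUE, TRUE, FALSE), group = "all")
  km <- km_estimate(recs)
  expect_equal(km$time, c(2, 5))
  expect_equal(km$survival, c(2 / 3, 1 / 3))
  expect_equal(km$cum_incidence, c(1 / 3, 2 / 3))
  expect_equal(km$n_risk, c(3, 2))

  # All censored: the curve never drops.
  km0 <- km_estimate(data.frame(time_months = c(3, 9),
                                event = c(FALSE, FALSE), group = "all"))
  expect_identical(nrow(km0), 0L)

  # No censoring: complement of the empirical CDF.
  t <- c(1, 2, 2, 5, 9)
  km1 <- km_estimate(data.frame(time_months = t, event = TRUE,
                                group = "all"))
  expect_equal(km1$survival,
               sapply(unique(sort(t)), function(u) mean(t > u)))
})

test_that("km_estimate equals brute-force risk-set recomputation (<=20 records)", {
  # Independent oracle: recompute risk sets and the product from scratch.
  brute_km <- function(time, event) {
    s <- 1
    out <- NULL
    for (u in sort(unique(time[event]))) {
      n_risk <- sum(time >= u)
      d <- sum(time == u & event)
      s <- s * (1 - d / n_risk)
      out <- rbind(out, c(u, s))
    }
    out
  }
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(1:20, 1)
    time <- sample(1:12, n, replace = TRUE)
    event <- runif(n) < 0.7
    km <- km_estimate(data.frame(time_months = time, event = event,
                                 group = "all"))
    ref <- brute_km(time, event)
    if (is.null(ref)) {
      expect_identical(nrow(km), 0L)
    } else {
      expect_equal(km$time, ref[, 1])
      expect_equal(km$survival, ref[, 2])
    }
  }
})

test_that("km_estimate agrees with the survival package", {
  skip_if_not_installed("survival")
  cohort <- margins_fixture()
  recs <- to_survival_records(cohort)
  km <- km_estimate(recs)
  sf <- survival::survfit(survival::Surv(time_months, event) ~ 1,
                          data = recs)
  ref <- summary(sf, times = km$time)
  expect_equal(km$survival, ref$surv)
  expect_equal(km$n_risk, ref$n.risk)
})

test_that("log_rank matches the hand observed-minus-expected computation", {
  # Two groups of 4; events marked e, censorings c:
  # g1: 1e 3e 5c 7e ; g2: 2e 3c 6e 8c
  recs <- data.frame(time_months = c(1, 3, 5, 7, 2, 3, 6, 8),
                     event = c(TRUE, TRUE, FALSE, TRUE,
                               TRUE, FALSE, TRUE, FALSE),
                     group = rep(c("g1", "g2"), each = 4))
  lr <- log_rank(recs)
  # Hand computation over risk sets at t = 1,2,3,6,7.
  U <- (1 - 4 / 8) + (0 - 3 / 7) + (1 - 3 / 6) + (0 - 1 / 3) + (1 - 1 / 2)
  V <- (4 * 4 / 8^2) + (3 * 4 / 7^2) + (3 * 3 / 6^2) + (1 * 2 / 3^2) +
    (1 * 1 / 2^2)
  expect_equal(lr$statistic, U^2 / V, tolerance = 1e-12)
  expect_identical(lr$df, 1L)

  # Identical groups: statistic 0, p = 1.
  same <- data.frame(time_months = rep(c(2, 5, 9), 2),
                     event = rep(c(TRUE, TRUE, FALSE), 2),
                     group = rep(c("a", "b"), each = 3))
  lr0 <- log_rank(same)
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p_value, 1)

  expect_error(log_rank(data.frame(time_months = 1:3, event = TRUE,
                                   group = "only")),
               "two groups")
})

test_that("log_rank is invariant to group relabeling and matches survdiff", {
  skip_if_not_installed("survival")
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    recs <- data.frame(time_months = sample(1:24, n, replace = TRUE),
                       event = runif(n) < 0.6,
                       group = sample(c("x", "y"), n, replace = TRUE))
    if (length(unique(recs$group)) < 2 || sum(recs$event) == 0) next
    lr <- log_rank(recs)
    swapped <- recs
    swapped$group <- ifelse(recs$group == "x", "y", "x")
    expect_equal(log_rank(swapped)$statistic, lr$statistic)
    sd <- survival::survdiff(survival::Surv(time_months, event) ~ group,
                             data = recs)
    expect_equal(lr$statistic, sd$chisq, tolerance = 1e-8)
  }
})

test_that("median_iqr summarizes published records only", {
  recs <- data.frame(time_months = c(1, 18, 90, 146),
                     event = c(TRUE, TRUE, TRUE, FALSE), group = "all")
  s <- median_iqr(recs)
  expect_equal(s$median, 18)
  expect_equal(s$min, 1)
  expect_equal(s$max, 90)
  expect_identical(s$n_events, 3L)

  one <- median_iqr(data.frame(time_months = 7, event = TRUE,
                               group = "all"))
  expect_equal(one$median, 7)
  expect_equal(one$q25, 7)
  expect_equal(one$q75, 7)
  expect_error(median_iqr(data.frame(time_months = 5, event = FALSE,
                                     group = "all")),
               "no publication events")
})

test_that("cumulative incidence is monotone and bounded by the crude proportion", {
  cohort <- generate_cohort(cohort_params(n_abstracts = 120L), seed = 23)
  recs <- to_survival_records(cohort)
  km <- km_estimate(recs)
  expect_true(all(diff(km$cum_incidence) >= 0))
  expect_true(all(km$survival >= 0 & km$survival <= 1))
  expect_true(all(diff(km$n_risk) <= 0))
  # With no late censoring before the horizon, the final cumulative
  # incidence cannot exceed the overall publication proportion.
  expect_lte(max(km$cum_incidence),
             mean(vapply(cohort, is_published, logical(1))) + 1e-12)
})
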