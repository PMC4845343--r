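test_that("percent_difference follows the definition exactly", {
  expect_equal(percent_difference(1.5, 1.2), 25)
  expect_equal(percent_difference(0.9, 1.2), -25)
  for (x in c(0.3, 1, 2.7)) expect_equal(percent_difference(x, x), 0)
  expect_error(percent_difference(1.5, 0), "undefined")
})

test_that("classify_pair covers the qualitative and quantitative cases", {
  # Significance flip on p-values alone is qualitative discordance.
  res <- classify_pair(mk_outcome(mk_ratio(1.5, p = 0.03)),
                       mk_outcome(mk_ratio(1.4, p = 0.21)))
  expect_identical(res$category, "qualitative")
  # Direction flip with both significant is qualitative.
  res <- classify_pair(mk_outcome(mk_ratio(1.5, p = 0.01)),
                       mk_outcome(mk_ratio(0.7, p = 0.02)))
  expect_identical(res$category, "qualitative")
  # Different significantly-favored arms are qualitative.
  res <- classify_pair(mk_outcome(mk_ratio(1.5, p = 0.01, favored = "A")),
                       mk_outcome(mk_ratio(1.5, p = 0.01, favored = "B")))
  expect_identical(res$category, "qualitative")
  # Small magnitude shift, same direction and significance.
  res <- classify_pair(mk_outcome(mk_ratio(1.10, p = 0.2)),
                       mk_outcome(mk_ratio(1.05, p = 0.3)))
  expect_identical(res$category, "quant_lt10")
  expect_equal(res$percent_difference, (1.10 - 1.05) / 1.05 * 100)
  # Only p-values, both on the same side of 0.05: amount unclear.
  res <- classify_pair(mk_outcome(mk_ratio(p = 0.01)),
                       mk_outcome(mk_ratio(p = 0.03)))
  expect_identical(res$category, "quant_unclear")
  # Identical estimates agree exactly.
  res <- classify_pair(mk_outcome(mk_ratio(1.25, p = 0.04)),
                       mk_outcome(mk_ratio(1.25, p = 0.04)))
  expect_identical(res$category, "exact_agreement")
  expect_equal(res$percent_difference, 0)
  # Estimates on different measures cannot be banded.
  res <- classify_pair(mk_outcome(mk_ratio(1.25, p = 0.2)),
                       mk_outcome(effect_estimate("difference_measure", 2.0,
                                                  p_value = 0.3)))
  expect_identical(res$category, "quant_unclear")
  # Unreported significance on either side makes the pair non-comparable.
  res <- classify_pair(mk_outcome(mk_ratio(1.25)),
                       mk_outcome(mk_ratio(1.25, p = 0.2)))
  expect_identical(res$category, "not_comparable")
})

test_that("band boundaries are <10, [10,20], >20 on a grid", {
  w <- 1.13  # full 2-decimal precision, so the printed-precision rule
             # cannot collapse grid points to exact agreement
  for (pd in c(0.5, 3, 9.9, 10, 12.5, 17, 20, 20.1, 25, 80)) {
    a <- w * (1 + pd / 100)
    res <- classify_pair(mk_outcome(mk_ratio(a, p = 0.2)),
                         mk_outcome(mk_ratio(w, p = 0.3)))
    apd <- abs(res$percent_difference)
    expected <- if (apd < 10) "quant_lt10"
    else if (apd <= 20) "quant_10to20"
    else "quant_gt20"
    expect_identical(res$category, expected, label = paste("pd =", pd))
    expect_equal(apd, pd, tolerance = 1e-9)
  }
})

test_that("exact agreement compares at the coarser reported precision", {
  # 1.5 printed against 1.47: at one decimal both print 1.5.
  res <- classify_pair(mk_outcome(mk_ratio(1.5, p = 0.2)),
                       mk_outcome(mk_ratio(1.47, p = 0.3)))
  expect_identical(res$category, "exact_agreement")
})

test_that("swapping the documents never changes qualitative vs quantitative", {
  set.seed(31)
  for (rep in 1:40) {
    v1 <- round(exp(runif(1, -0.6, 0.8)), 2)
    v2 <- round(exp(runif(1, -0.6, 0.8)), 2)
    p1 <- round(runif(1), 2)
    p2 <- round(runif(1), 2)
    o1 <- mk_outcome(mk_ratio(v1, p = p1))
    o2 <- mk_outcome(mk_ratio(v2, p = p2))
    r12 <- classify_pair(o1, o2)
    r21 <- classify_pair(o2, o1)
    expect_identical(r12$category == "qualitative",
                     r21$category == "qualitative")
    if (!is.na(r12$percent_difference) && r12$percent_difference != 0 &&
        !is.na(r21$percent_difference))
      expect_identical(sign(r12$percent_difference),
                       -sign(r21$percent_difference))
  }
})

test_that("summarize_concordance reproduces the category mix of its fixture", {
  pairs <- generate_pair_fixture()  # published 86-pair mix
  s_exact <- summarize_concordance(pairs, "exact")
  expect_identical(unname(s_exact$counts),
                   c(39L, 7L, 14L, 5L, 14L, 7L))
  expect_identical(s_exact$n_comparable, 86L)
  expect_identical(s_exact$n_discordant, 47L)
  expect_equal(s_exact$prop_discordant, 47 / 86)

  s_lt10 <- summarize_concordance(pairs, "exact_or_lt10")
  expect_identical(s_lt10$n_discordant, 33L)
  expect_equal(s_lt10$prop_discordant, 33 / 86)
  # Switching the definition only moves quant_lt10 across the line.
  expect_identical(s_lt10$counts, s_exact$counts)
  expect_identical(s_exact$n_discordant - s_lt10$n_discordant,
                   unname(s_exact$counts["quant_lt10"]))
})

test_that("an all-identical cohort agrees 100% under both definitions", {
  pairs <- generate_pair_fixture(c(exact = 10, qualitative = 0, lt10 = 0,
                                   `10to20` = 0, gt20 = 0, unclear = 0))
  for (def in c("exact", "exact_or_lt10")) {
    s <- summarize_concordance(pairs, def)
    expect_equal(s$prop_agree, 1)
  }
})

test_that("match_status gates on domain, time point, and reported results", {
  base <- mk_pair(cls = "significant")
  expect_true(match_status(base)$comparable)

  # Different time point.
  p2 <- base
  p2$publication$outcomes[[1]]$time_value <- 12
  ms <- match_status(p2)
  expect_true(ms$same_domain)
  expect_false(ms$same_time_point)
  expect_false(ms$comparable)

  # Same time point expressed in different units still matches.
  p3 <- base
  p3$abstract$outcomes[[1]]$time_value <- 0.5
  p3$abstract$outcomes[[1]]$time_unit <- "years"
  p3$publication$outcomes[[1]]$time_value <- 6
  expect_true(match_status(p3)$comparable)

  # Different domain, rescued by a synonym map.
  p4 <- base
  p4$publication$outcomes[[1]]$domain <- "IOP"
  expect_false(match_status(p4)$same_domain)
  expect_true(match_status(p4, synonyms = c(
    IOP = "intraocular pressure"))$same_domain)

  # Unpublished pairs are never comparable.
  expect_false(match_status(mk_pair(published = FALSE))$comparable)
})
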