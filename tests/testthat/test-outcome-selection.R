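test_that("the four selection rules fire in hierarchy order", {
  sig <- function(order, ...) mk_outcome(mk_ratio(1.4, p = 0.03),
                                         order = order, ...)
  # Rule 1: a single designated primary wins even when another outcome is
  # titled or earlier in Results.
  ch <- select_main_outcome(list(sig(1, titled = TRUE),
                                 sig(2, primary = TRUE)))
  expect_identical(ch$outcome_index, 2L)
  expect_identical(ch$rule_applied, 1L)
  # Rule 2: several primaries -> earliest in Results among them.
  ch <- select_main_outcome(list(sig(3, primary = TRUE), sig(1),
                                 sig(2, primary = TRUE)))
  expect_identical(ch$outcome_index, 3L)
  expect_identical(ch$rule_applied, 2L)
  # Rule 3: no primary -> title/objective mention (earliest among several).
  ch <- select_main_outcome(list(sig(2, titled = TRUE), sig(1),
                                 sig(3, titled = TRUE)))
  expect_identical(ch$outcome_index, 1L)
  expect_identical(ch$rule_applied, 3L)
  # Rule 4: nothing designated or titled -> first in Results.
  ch <- select_main_outcome(list(sig(2), sig(1)))
  expect_identical(ch$outcome_index, 2L)
  expect_identical(ch$rule_applied, 4L)

  expect_error(select_main_outcome(list()), "no outcomes")
  expect_error(select_main_outcome(list(sig(1), sig(1))), "unique")
})

test_that("selection is invariant to permutation of the outcomes list", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(2:5, 1)
    outcomes <- lapply(seq_len(n), function(i)
      mk_outcome(mk_ratio(1.2, p = 0.2), order = i,
                 primary = runif(1) < 0.3, titled = runif(1) < 0.4))
    ref <- select_main_outcome(outcomes)
    ref_outcome <- outcomes[[ref$outcome_index]]
    perm <- sample(n)
    got <- select_main_outcome(outcomes[perm])
    expect_identical(outcomes[perm][[got$outcome_index]], ref_outcome)
    expect_identical(got$rule_applied, ref$rule_applied)
  }
})

test_that("rules 2 and 4 match a brute-force argmin over candidates", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    orders <- sample(100, n)
    n_primary <- sample(c(0, 2, 3), 1)
    primary <- seq_len(n) %in% sample(n, min(n_primary, n))
    outcomes <- lapply(seq_len(n), function(i)
      mk_outcome(mk_ratio(1.2, p = 0.2), order = orders[i],
                 primary = primary[i]))
    ch <- select_main_outcome(outcomes)
    candidates <- if (any(primary)) which(primary) else seq_len(n)
    brute <- candidates[which.min(orders[candidates])]
    if (sum(primary) != 1 && ch$rule_applied %in% c(2L, 4L))
      expect_identical(ch$outcome_index, brute)
  }
})

test_that("the rule census partitions the cohort", {
  cohort <- list(
    pair_record(abstract_record("a1", 2002, authors = list(coi_profile()),
                                outcomes = list(mk_outcome(mk_ratio(1.2, p = 0.3),
                                                           primary = TRUE))),
                followup_months = 134L),
    pair_record(abstract_record("a2", 2002, authors = list(coi_profile()),
                                outcomes = list(mk_outcome(mk_ratio(1.2, p = 0.3),
                                                           titled = TRUE))),
                followup_months = 134L),
    pair_record(abstract_record("a3", 2002, authors = list(coi_profile()),
                                outcomes = list(mk_outcome(mk_ratio(1.2, p = 0.3)))),
                followup_months = 134L))
  census <- selection_rule_census(cohort)
  expect_identical(as.vector(census), c(1L, 0L, 1L, 1L))
  expect_identical(sum(census), length(cohort))
  expect_error(selection_rule_census(list()), "empty")
})

test_that("census proportions on a generated cohort track the rule mix", {
  params <- cohort_params()
  cohort <- generate_cohort(params, seed = 5)
  census <- selection_rule_census(cohort)
  props <- attr(census, "proportion")
  target <- c(params$rule_mix["rule1"], 0, params$rule_mix["rule3"],
              params$rule_mix["rule4"])
  # Binomial sampling error at n = 513: 3 sd of the largest class is
  # about 0.064.
  expect_lt(max(abs(unname(props) - unname(target))), 0.07)
  expect_identical(sum(census), length(cohort))
})
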