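test_that("record constructors enforce their invariants", {
  expect_error(effect_estimate("ratio_measure", -1), "positive")
  expect_error(effect_estimate("ratio_measure", 1.2, ci_low = 2, ci_high = 1),
               "ci_low")
  expect_error(effect_estimate("ratio_measure", 1.2, p_value = 1.5),
               "p_value")
  expect_error(outcome_report("iop", 6, results_order = 0L,
                              comparisons = list(mk_ratio(1.2))),
               "positive integer")
  expect_error(outcome_report("iop", 6, results_order = 1L),
               "comparisons or a significance claim")
  expect_error(abstract_record("a", 2002, funding = c("none", "industry"),
                               authors = list(coi_profile()),
                               outcomes = list(mk_outcome(mk_ratio(1.2)))),
               "singleton")
  expect_error(abstract_record("a", 2002, funding = "charity",
                               authors = list(coi_profile()),
                               outcomes = list(mk_outcome(mk_ratio(1.2)))),
               "unknown funding")
  expect_error(
    abstract_record("a", 2002,
                    authors = list(coi_profile(disclosure_level = "team_aggregate")),
                    outcomes = list(mk_outcome(mk_ratio(1.2)))),
    "2001")
  expect_error(
    abstract_record("a", 2002, authors = list(coi_profile()),
                    outcomes = list(mk_outcome(mk_ratio(1.2), order = 1L),
                                    mk_outcome(mk_ratio(1.3), order = 1L))),
    "unique")
  expect_error(publication_record("p", 0L, list(mk_outcome(mk_ratio(1.2)))),
               "integer >= 1")
  expect_error(pair_record(mk_pair()$abstract,
                           publication_record("p", 50L,
                                              list(mk_outcome(mk_ratio(1.2)))),
                           followup_months = 40L),
               "followup_months")
})

test_that("cohort round-trips through CSV and JSON on all fields", {
  cohort <- generate_cohort(cohort_params(n_abstracts = 25L), seed = 11)
  for (fmt in c("csv", "json")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_cohort(cohort, path, fmt)
    back <- read_cohort(path, fmt)
    expect_identical(back, cohort, label = paste("round trip via", fmt))
  }
})

test_that("a minimal one-row file parses to a one-pair cohort", {
  cohort <- list(mk_pair(published = FALSE, id = "solo"))
  path <- tempfile(fileext = ".csv")
  write_cohort(cohort, path, "csv")
  got <- read_cohort(path)
  expect_length(got, 1L)
  expect_identical(got[[1]]$abstract$abstract_id, "solo")
})

test_that("publication months below 1 are coerced to 1 with a note", {
  cohort <- list(mk_pair(months = 2L, id = "early"))
  path <- tempfile(fileext = ".csv")
  write_cohort(cohort, path, "csv")
  txt <- readLines(path)
  txt <- gsub(",2,", ",0,", txt, fixed = TRUE)  # months column
  writeLines(txt, path)
  expect_message(got <- read_cohort(path), "coerced to 1")
  expect_identical(got[[1]]$publication$months_after_presentation, 1L)
})

test_that("malformed files fail with locatable errors", {
  cohort <- list(mk_pair(id = "ok1"), mk_pair(id = "ok2"))
  path <- tempfile(fileext = ".csv")
  write_cohort(cohort, path, "csv")
  df <- utils::read.csv(path, colClasses = c(abstract_id = "character"))

  bad <- df
  bad$abstract_id[2] <- NA
  p1 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, p1, row.names = FALSE, na = "")
  expect_error(read_cohort(p1), "missing abstract_id")

  bad <- df
  bad$presentation[bad$abstract_id == "ok2"] <- "keynote"
  p2 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, p2, row.names = FALSE, na = "")
  expect_error(read_cohort(p2), "ok2")

  bad <- df[, setdiff(names(df), "results_order")]
  p3 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, p3, row.names = FALSE, na = "")
  expect_error(read_cohort(p3), "results_order")
})

test_that("write_results is deterministic and formats RRs to 2 decimals", {
  cohort <- margins_fixture()
  path <- tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  cfg <- pipeline_config(input = path, seed = 3L)
  bundle <- run_pipeline(cfg)

  d1 <- tempfile(); d2 <- tempfile()
  f1 <- write_results(bundle, d1)
  f2 <- write_results(bundle, d2)
  expect_identical(lapply(f1, readLines), lapply(f2, readLines))

  # Formatting contract: an RR of exactly 1.0 renders as "1.00".
  bundle$rr_table$rr[1] <- 1.0
  f3 <- write_results(bundle, tempfile())
  rr_csv <- readLines(grep("rr_table", f3, value = TRUE))
  expect_match(rr_csv[2], "\"1\\.00\"")
})
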