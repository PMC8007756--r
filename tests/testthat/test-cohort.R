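test_that("each inclusion filter removes its planted case at the right step", {
  idx <- as.Date("2015-03-02")
  cdm <- tiny_cdm(persons = 4, index_date = idx)
  # person 2: a 17-year-old at the test
  cdm$person$year_of_birth[2] <- 1998
  # person 3: observation ends 500 days after index (no full time-at-risk)
  cdm$observation_period$observation_period_end_date[3] <- idx + 500
  # person 4: outcome 10 days before index
  cdm$condition_occurrence <- tibble::tibble(
    condition_occurrence_id = 1, person_id = 4, condition_concept_id = 0,
    condition_start_date = idx - 10, condition_end_date = idx - 10,
    condition_source_value = "I63.9")
  coh <- build_target_cohort(cdm, cohort_definition(min_lookback = 90))
  expect_equal(coh$attrition$n_remaining, c(4, 3, 3, 2, 1, 1))
  expect_equal(coh$entries$person_id, 1)
  expect_equal(coh$entries$tar_start, idx + 1)
  expect_equal(coh$entries$tar_end, idx + 1095)
})

test_that("only the configured study type enters the cohort", {
  cdm <- tiny_cdm(persons = 2)
  cdm$procedure_occurrence$procedure_concept_id[2] <- 4300004  # an MSLT
  coh <- build_target_cohort(cdm)
  expect_equal(coh$attrition$n_remaining[1], 1)
})

test_that("attrition is monotone non-increasing on generated data", {
  p <- demo_pipeline(n = 2000, seed = 3)
  for (lb in c(30, 90, 180)) {
    coh <- build_target_cohort(p$cdm, cohort_definition(min_lookback = lb))
    expect_true(all(diff(coh$attrition$n_remaining) <= 0), label = paste(lb))
    expect_true(all(coh$attrition$n_removed >= 0))
  }
  # stricter lookback cannot enlarge the cohort
  n_by_lb <- vapply(c(30, 90, 180), function(lb) {
    nrow(build_target_cohort(p$cdm,
                             cohort_definition(min_lookback = lb))$entries)
  }, numeric(1))
  expect_true(all(diff(n_by_lb) <= 0))
})

test_that("empty CDM gives an empty cohort with a ledger of zeros", {
  coh <- build_target_cohort(cdm_bundle())
  expect_equal(nrow(coh$entries), 0L)
  expect_true(all(coh$attrition$n_remaining == 0))
})

test_that("outcome labels respect the inclusive time-at-risk boundaries", {
  idx <- as.Date("2015-03-02")
  entries <- tibble::tibble(person_id = c(1, 2, 3), index_date = idx,
                            tar_start = idx + 1, tar_end = idx + 1095)
  conditions <- tibble::tibble(
    person_id = c(1, 2, 3),
    condition_source_value = c("I63.9", "I63.9", "Z00.0"),
    condition_start_date = c(idx + 400, idx + 1200, idx + 400))
  lab <- label_outcomes(entries, outcome_definition(), conditions)
  expect_equal(lab$label, c(1L, 0L, 0L))
})

test_that("no positive label lacks a qualifying event inside time-at-risk", {
  p <- demo_pipeline(n = 2000, seed = 3)
  coh <- build_target_cohort(p$cdm)
  lab <- label_outcomes(coh$entries, outcome_definition(),
                        p$cdm$condition_occurrence)
  qual <- p$cdm$condition_occurrence[
    grepl("^(I1[0-5]|I2[0-5]|I48|I6[0-9]|E0[89]|E1[0-4])",
          p$cdm$condition_occurrence$condition_source_value), ]
  pos <- lab[lab$label == 1, ]
  joined <- dplyr::inner_join(pos, qual, by = "person_id",
                              relationship = "many-to-many")
  in_tar <- joined$condition_start_date >= joined$tar_start &
    joined$condition_start_date <= joined$tar_end
  expect_true(all(tapply(in_tar, joined$person_id, any)))
})

test_that("the outcome rate is the printed percentage arithmetic", {
  idx <- as.Date("2015-01-01")
  entries <- tibble::tibble(person_id = 1:639, index_date = idx,
                            tar_start = idx + 1, tar_end = idx + 1095)
  conditions <- tibble::tibble(person_id = 1:71,
                               condition_source_value = "I10",
                               condition_start_date = idx + 400)
  lab <- label_outcomes(entries, outcome_definition(), conditions)
  expect_equal(sum(lab$label), 71L)
  expect_equal(attr(lab, "outcome_rate"), 11.11)
})

test_that("invalid outcome codes and time-at-risk windows are rejected", {
  expect_error(outcome_definition("banana"), class = "sleepcdm_config_error")
  expect_error(cohort_definition(tar_start = 0), class = "sleepcdm_config_error")
})
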