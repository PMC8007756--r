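labelled_cohort <- function(p) {
  coh <- build_target_cohort(p$cdm)
  label_outcomes(coh$entries, outcome_definition(), p$cdm$condition_occurrence)
}

test_that("value covariates use the most recent in-window value", {
  idx <- as.Date("2015-03-02")
  cdm <- tiny_cdm()
  cdm$measurement <- tibble::tibble(
    measurement_id = c(1, 2), person_id = 1,
    measurement_concept_id = 3050001,
    measurement_date = c(idx - 100, idx - 10),
    value_as_number = c(200, 150), unit_concept_id = 0,
    visit_occurrence_id = NA_real_, measurement_source_value = "LAB_TG",
    modifier_of_event_id = NA_real_, modifier_of_field_concept_id = NA_real_)
  cdm$drug_era <- tibble::tibble(
    drug_era_id = 1, person_id = 1, drug_concept_id = 21600396,
    drug_era_start_date = idx - 200, drug_era_end_date = idx - 3,
    drug_source_value = "A03AC")
  entries <- tibble::tibble(person_id = 1, index_date = idx, age = 45,
                            label = 1L)
  vocab <- build_psg_vocabulary(psg_parameter_catalog())
  cv <- suppressMessages(
    extract_covariates(entries, cdm, vocab, covariate_settings("all")))
  tg180 <- cv$x[1, grep("-180.*LAB_TG", colnames(cv$x))]
  expect_equal(unname(tg180), 150)  # the day -10 value, not day -100
  # era overlapping the [-7, 0] window: indicator 1
  a03 <- cv$x[1, grep("day -7.*A03AC", colnames(cv$x))]
  expect_equal(unname(a03), 1)
})

test_that("windows that extend past the index date are rejected", {
  expect_error(covariate_settings("all", windows = list(c(-7, 2))),
               class = "sleepcdm_config_error")
})

test_that("psg_only uses only gender, age group and PSG parameters", {
  p <- demo_pipeline(n = 500, seed = 21)
  lab <- labelled_cohort(p)
  cv <- suppressMessages(
    extract_covariates(lab, p$cdm, p$vocab, covariate_settings("psg_only")))
  fams <- colnames(cv$x)
  expect_true(all(grepl("^(gender|age group|measurement value)", fams)))
  # every measurement-value column is a catalog parameter, never a lab
  meas_cols <- fams[grepl("^measurement value", fams)]
  expect_false(any(grepl("LAB_", meas_cols)))
})

test_that("no covariate looks past day 0: post-index data are inert", {
  p <- demo_pipeline(n = 500, seed = 21)
  lab <- labelled_cohort(p)
  cv1 <- suppressMessages(
    extract_covariates(lab, p$cdm, p$vocab, covariate_settings("all")))

  idx_of <- lab$index_date[match(p$cdm$condition_occurrence$person_id,
                                 lab$person_id)]
  post <- !is.na(idx_of) &
    p$cdm$condition_occurrence$condition_start_date > idx_of
  cdm2 <- p$cdm
  set.seed(99)
  # scramble every post-index condition and add noise measurements after index
  cdm2$condition_occurrence$condition_source_value[post] <-
    sample(c("I10", "C34.9", "Z99.9"), sum(post), replace = TRUE)
  cdm2$condition_occurrence$condition_start_date[post] <-
    cdm2$condition_occurrence$condition_start_date[post] + sample(1:200, sum(post), TRUE)
  extra <- tibble::tibble(
    measurement_id = max(cdm2$measurement$measurement_id) + seq_len(nrow(lab)),
    person_id = lab$person_id, measurement_concept_id = 3050001,
    measurement_date = lab$index_date + 5, value_as_number = 9999,
    unit_concept_id = 0, visit_occurrence_id = NA_real_,
    measurement_source_value = "LAB_TG", modifier_of_event_id = NA_real_,
    modifier_of_field_concept_id = NA_real_)
  cdm2$measurement <- dplyr::bind_rows(cdm2$measurement, extra)

  cv2 <- suppressMessages(
    extract_covariates(lab, cdm2, p$vocab, covariate_settings("all")))
  expect_identical(cv1$x, cv2$x)
})

test_that("zero-variance columns are dropped with a log line", {
  p <- demo_pipeline(n = 500, seed = 21)
  lab <- labelled_cohort(p)
  expect_message(
    cv <- extract_covariates(lab, p$cdm, p$vocab, covariate_settings("all")),
    "zero-variance")
  expect_true(all(apply(cv$x, 2, stats::var) > 0))
})
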