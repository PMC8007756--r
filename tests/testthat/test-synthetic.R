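test_that("severity bands partition the AHI axis at the printed boundaries", {
  expect_equal(as.character(classify_osa_severity(c(4.9, 5, 14.9, 15, 17.3,
                                                    29.9, 30, 0))),
               c("normal", "mild", "mild", "moderate", "moderate",
                 "moderate", "severe", "normal"))
  expect_error(classify_osa_severity(-1), class = "sleepcdm_domain_error")
  # exactly one class per value over a random grid
  set.seed(1)
  v <- runif(500, 0, 120)
  expect_false(anyNA(classify_osa_severity(v)))
})

test_that("generation is reproducible and respects its config contract", {
  cfg <- generator_config(150, seed = 42)
  g1 <- generate_sleep_ehr(cfg)
  g2 <- generate_sleep_ehr(cfg)
  expect_identical(g1$reports, g2$reports)
  expect_identical(g1$truth, g2$truth)
  expect_identical(g1$cdm$measurement, g2$cdm$measurement)

  expect_error(generator_config(10), class = "sleepcdm_config_error")
  expect_error(generator_config(10, seed = 1,
                                study_type_mix = c("full-night" = 0.9)),
               class = "sleepcdm_config_error")
})

test_that("an empty generation request yields an empty bundle", {
  g <- generate_sleep_ehr(generator_config(0, seed = 1))
  expect_equal(nrow(g$reports), 0L)
  expect_equal(nrow(g$cdm$person), 0L)
  expect_equal(nrow(g$truth), 0L)
})

test_that("sampled margins converge to the configured mixes", {
  g <- demo_pipeline(n = 4000, seed = 9)$gen
  male <- mean(g$cdm$person$gender_concept_id == 8507)
  expect_lt(abs(male - 8363 / 11392), 0.025)
  sev <- table(classify_osa_severity(g$truth$ahi)) / nrow(g$truth)
  expect_lt(abs(sev[["severe"]] - 3193 / 11250), 0.025)
  expect_lt(abs(sev[["normal"]] - 3209 / 11250), 0.025)
  types <- table(g$truth$study_type) / nrow(g$truth)
  expect_lt(abs(types[["full-night"]] - 7191 / 11797), 0.03)
})

test_that("every generated report references a generated order and person", {
  g <- demo_pipeline(n = 500, seed = 21)$gen
  expect_true(all(g$reports$source_person_id %in%
                    g$cdm$person$person_source_value))
  expect_equal(nrow(g$reports), nrow(g$cdm$procedure_occurrence))
  expect_equal(nrow(validate_referential_integrity(g$cdm)), 0L)
})

test_that("planted outcome model is recoverable from ground truth", {
  # logistic refit on the truth table recovers the AHI coefficient sign
  signs <- vapply(1:10, function(s) {
    g <- generate_sleep_ehr(generator_config(1200, seed = 100 + s))
    fit <- stats::glm(event ~ age_at_test + ahi + low_spo2 +
                        comorbidity_count,
                      family = stats::binomial(), data = g$truth)
    sign(stats::coef(fit)[["ahi"]])
  }, numeric(1))
  expect_true(all(signs == 1))
})

test_that("demographic summary reproduces the published percentages", {
  d <- summarize_demographics(reference_sleep_test_records())
  val <- function(sec, lev, col = "pct_records") {
    d[[col]][d$section == sec & d$level == lev]
  }
  expect_equal(val("gender", "male"), 73.4)
  expect_equal(val("gender", "female"), 26.6)
  expect_equal(val("osa_severity", "normal"), 28.5)
  expect_equal(val("osa_severity", "mild"), 23.8)
  expect_equal(val("osa_severity", "moderate"), 19.3)
  expect_equal(val("age_group", "50-59"), 25.0)
  expect_equal(attr(d, "tests_per_person"), 1.2)
  expect_equal(attr(d, "n_ahi_records"), 11250L)
  expect_equal(d$n_records[d$section == "total"], 11392L)
  expect_equal(d$n_persons[d$section == "total"], 9577L)
})

test_that("a single record owns all of its categories", {
  one <- tibble::tibble(test_id = 1L, person_id = 1L, gender = "male",
                        age = 55L, study_year = 2015L, ahi = 12)
  d <- summarize_demographics(one)
  expect_true(all(d$pct_records == 100))
  expect_equal(attr(d, "tests_per_person"), 1)
})

test_that("half-up rounding follows the printed-percentage convention", {
  expect_equal(round_half_up(28.45, 1), 28.5)
  expect_equal(round_half_up(11.115, 2), 11.12)
  expect_equal(round_half_up(c(1.25, -1.25), 1), c(1.3, -1.3))
})
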