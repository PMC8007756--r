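catalog <- psg_parameter_catalog()
rules <- default_rule_set(catalog)
vocab <- build_psg_vocabulary(catalog)

meas_row <- function(code, value, id = 1, event = 1) {
  tibble::tibble(
    measurement_id = id, person_id = 1,
    measurement_concept_id = resolve_source_code(code, vocab),
    measurement_date = as.Date("2015-03-02"), value_as_number = value,
    unit_concept_id = 0, visit_occurrence_id = 1,
    measurement_source_value = code,
    modifier_of_event_id = event, modifier_of_field_concept_id = 1147082)
}

test_that("default rule set covers every parameter family", {
  oxygen <- catalog$parameter_name[catalog$category == "Oxygen statistics"]
  expect_equal(sum(rules$parameter_name %in% oxygen), 8L)
  expect_true(any(rules$kind == "cross-field"))
  pct <- rules[rules$kind == "percentage-bounds", ]
  expect_true(all(pct$lower == 0 & pct$upper == 100))
  spo2 <- rules[rules$parameter_name == "Lowest oxygen saturation (%)", ]
  expect_true(spo2$lower_open)  # (0, 100]
  bmi <- rules[rules$parameter_name == "Body mass index (BMI)", ]
  expect_equal(c(bmi$lower, bmi$upper), c(10, 100))
  expect_equal(nrow(default_rule_set(catalog[0, ])), 0L)
})

test_that("out-of-bounds values are removed and attributed to their rule", {
  m <- dplyr::bind_rows(
    meas_row("SE_PCT", 104, id = 1),   # sleep efficiency over 100%
    meas_row("AHI_TOTAL", -2, id = 2), # negative index
    meas_row("LOW_SPO2", 0, id = 3),   # saturation must exceed 0
    meas_row("TST_MIN", 400, id = 4))
  res <- apply_rules(m, rules, catalog)
  expect_equal(sort(res$removed$measurement_id), c(1, 2, 3))
  expect_equal(nrow(res$kept), 1L)
  se_rule <- rules$rule_id[rules$parameter_name == "Sleep efficiency (SE) (%)"]
  expect_equal(res$removed$rule_id[res$removed$measurement_id == 1], se_rule)
  expect_equal(sum(res$ledger$n_removed), nrow(res$removed))
})

test_that("the cross-field rule removes total sleep time exceeding time in bed", {
  m <- dplyr::bind_rows(
    meas_row("TST_MIN", 500, id = 1),
    meas_row("TIB_MIN", 450, id = 2))
  res <- apply_rules(m, rules, catalog)
  expect_equal(res$removed$measurement_source_value, "TST_MIN")
  ok <- dplyr::bind_rows(
    meas_row("TST_MIN", 420, id = 1),
    meas_row("TIB_MIN", 450, id = 2))
  expect_equal(nrow(apply_rules(ok, rules, catalog)$removed), 0L)
})

test_that("cleaning partitions the input and is idempotent on kept rows", {
  p <- demo_pipeline(n = 500, seed = 21)
  res <- apply_rules(p$cdm$measurement, rules, catalog)
  expect_equal(nrow(res$kept) + nrow(res$removed), nrow(p$cdm$measurement))
  expect_equal(sum(res$ledger$n_removed), nrow(res$removed))
  again <- apply_rules(res$kept, rules, catalog)
  expect_equal(nrow(again$removed), 0L)
  expect_equal(again$kept, res$kept)
})

test_that("adding a rule never increases the kept set", {
  p <- demo_pipeline(n = 500, seed = 21)
  base <- apply_rules(p$cdm$measurement, rules, catalog)
  stricter <- dplyr::bind_rows(rules, tibble::tibble(
    rule_id = "R999", parameter_name = "Apnea hypopnea index (AHI) (/h)",
    kind = "range", lower = 0, upper = 10, lower_open = FALSE,
    upper_open = FALSE, action = "remove"))
  res <- apply_rules(p$cdm$measurement, stricter, catalog)
  expect_lte(nrow(res$kept), nrow(base$kept))
})

test_that("rules referencing unknown parameters are a configuration error", {
  bad <- tibble::tibble(rule_id = "RX", parameter_name = "No such parameter",
                        kind = "range", lower = 0, upper = 1,
                        lower_open = FALSE, upper_open = FALSE,
                        action = "remove")
  expect_error(apply_rules(empty_measurements(), bad, catalog),
               class = "sleepcdm_config_error")
})

empty_measurements <- function() meas_row("AHI_TOTAL", 1)[0, ]
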