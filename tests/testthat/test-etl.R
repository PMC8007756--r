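vocab <- build_psg_vocabulary(psg_parameter_catalog())

test_that("extraction renames dialect fields and applies unit conversions", {
  rec <- tiny_report(form_version = 3, fields = list(AHI_TOTAL = 32.1))
  out <- extract_report(rec)
  expect_equal(out$parameter_name, "Apnea hypopnea index (AHI) (/h)")
  expect_equal(out$value, 32.1)

  # version-1 dialect: lower-case dotted names, height in metres
  rec <- tiny_report(form_version = 1, fields = list(ht = 1.72))
  out <- extract_report(rec)
  expect_equal(out$parameter_name, "Body height (cm)")
  expect_equal(out$value, 172)

  expect_error(extract_report(tiny_report(form_version = 12)),
               class = "sleepcdm_unknown_version")
})

test_that("unmappable fields are skipped with a warning, never zero-filled", {
  rec <- tiny_report(form_version = 3,
                     fields = list(AHI_TOTAL = 10, BOGUS_FIELD = 5))
  expect_warning(out <- extract_report(rec), "BOGUS_FIELD")
  expect_equal(nrow(out), 1L)
  expect_equal(attr(out, "skipped_fields"), "BOGUS_FIELD")
})

test_that("procedure linkage matches by date with deterministic tie-breaks", {
  cdm <- tiny_cdm()
  rep <- tiny_report(study_date = as.Date("2015-03-02"))
  link <- link_to_procedure(rep, cdm)
  expect_equal(link$procedure_occurrence_id, 1)
  expect_true(is.na(link$reason))

  # two same-day candidates: lowest id wins
  cdm2 <- tiny_cdm()
  cdm2$procedure_occurrence <- dplyr::bind_rows(
    cdm2$procedure_occurrence,
    dplyr::mutate(cdm2$procedure_occurrence, procedure_occurrence_id = 2))
  expect_equal(link_to_procedure(rep, cdm2)$procedure_occurrence_id, 1)

  # nearest date wins over a farther one
  cdm3 <- tiny_cdm()
  cdm3$procedure_occurrence <- tibble::tibble(
    procedure_occurrence_id = c(1, 2), person_id = 1,
    procedure_concept_id = 4300001,
    procedure_date = as.Date(c("2015-03-01", "2015-03-02")),
    visit_occurrence_id = 1)
  expect_equal(link_to_procedure(rep, cdm3)$procedure_occurrence_id, 2)

  # out-of-window order: quarantined with the stated reason
  far <- tiny_report(study_date = as.Date("2015-06-01"))
  expect_equal(link_to_procedure(far, cdm)$reason, "no matching order")
})

test_that("load produces one row per populated parameter plus the linkage", {
  cdm <- tiny_cdm()
  rec <- tiny_report(form_version = 4,
                     fields = list(AHI_TOTAL = 32.1, TST_MIN = 370,
                                   SE_PCT = 88.1, WHR = 0.95))
  res <- transform_and_load(rec, vocab, cdm)
  expect_equal(res$summary$measurements_added, 3L)
  expect_equal(res$summary$observations_added, 1L)
  expect_true(all(res$cdm$measurement$modifier_of_event_id == 1))
  expect_true(all(res$cdm$measurement$modifier_of_field_concept_id == 1147082))
  expect_equal(res$cdm$observation$observation_event_id, 1)
  expect_equal(nrow(validate_referential_integrity(res$cdm)), 0L)
})

test_that("re-loading an already loaded report adds nothing", {
  cdm <- tiny_cdm()
  rec <- tiny_report(fields = list(AHI_TOTAL = 20, TST_MIN = 400))
  once <- transform_and_load(rec, vocab, cdm)
  twice <- transform_and_load(rec, vocab, once$cdm)
  expect_equal(twice$summary$already_loaded, 1L)
  expect_equal(twice$summary$measurements_added, 0L)
  expect_equal(nrow(twice$cdm$measurement), nrow(once$cdm$measurement))
})

test_that("reports without a linkable order are quarantined, not loaded", {
  cdm <- tiny_cdm()
  cdm$procedure_occurrence <- cdm$procedure_occurrence[0, ]
  rec <- tiny_report(fields = list(AHI_TOTAL = 20))
  res <- transform_and_load(rec, vocab, cdm)
  expect_equal(res$summary$quarantined, 1L)
  expect_equal(res$quarantined$reason, "no matching order")
  expect_equal(nrow(res$cdm$measurement), 0L)
  # quarantined reports stay retryable: not in the ledger
  expect_equal(nrow(res$cdm$etl_ledger), 0L)
})

test_that("load conserves rows: loaded = populated mapped - quarantined", {
  p <- demo_pipeline(n = 500, seed = 21)
  populated <- sum(lengths(p$gen$reports$fields))
  loaded <- p$summary$measurements_added + p$summary$observations_added
  expect_equal(p$summary$quarantined, 0L)
  expect_equal(p$summary$fields_skipped, 0L)
  expect_equal(loaded, populated)
  expect_equal(nrow(validate_referential_integrity(p$cdm)), 0L)
})

test_that("source reports round-trip through the delimited interchange", {
  p <- demo_pipeline(n = 300, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_source_reports(p$gen$reports, path)
  back <- read_source_reports(path)
  expect_equal(nrow(back), nrow(p$gen$reports))
  orig <- p$gen$reports[order(p$gen$reports$report_id), ]
  i <- 5
  expect_equal(sort(names(back$fields[[i]])), sort(names(orig$fields[[i]])))
  expect_equal(unlist(back$fields[[i]])[names(orig$fields[[i]])],
               unlist(orig$fields[[i]]), tolerance = 1e-9)
})
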