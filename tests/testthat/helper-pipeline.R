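# Shared fixtures, built in code and cached per test run.

.pipeline_cache <- new.env(parent = emptyenv())

# vocabulary + generated EHR + loaded CDM, memoized on (n, seed)
demo_pipeline <- function(n = 2000, seed = 3) {
  key <- sprintf("p%d_%d", n, seed)
  if (!exists(key, envir = .pipeline_cache)) {
    vocab <- build_psg_vocabulary(psg_parameter_catalog())
    gen <- generate_sleep_ehr(generator_config(n, seed = seed))
    res <- suppressWarnings(transform_and_load(gen$reports, vocab, gen$cdm))
    assign(key, list(vocab = vocab, gen = gen, cdm = res$cdm,
                     summary = res$summary, quarantined = res$quarantined),
           envir = .pipeline_cache)
  }
  get(key, envir = .pipeline_cache)
}

# minimal hand-built CDM bundle: one person, one visit, one full-night
# procedure; extra rows supplied by the caller
tiny_cdm <- function(persons = 1, index_date = as.Date("2015-03-02"),
                     year_of_birth = 1970) {
  ids <- seq_len(persons)
  cdm_bundle(
    person = tibble::tibble(
      person_id = as.numeric(ids), gender_concept_id = 8507,
      year_of_birth = year_of_birth,
      person_source_value = sprintf("SRC%06d", ids)),
    observation_period = tibble::tibble(
      observation_period_id = as.numeric(ids), person_id = as.numeric(ids),
      observation_period_start_date = index_date - 2000,
      observation_period_end_date = index_date + 2000),
    visit_occurrence = tibble::tibble(
      visit_occurrence_id = as.numeric(ids), person_id = as.numeric(ids),
      visit_concept_id = 9201, visit_start_date = index_date,
      visit_end_date = index_date + 1),
    procedure_occurrence = tibble::tibble(
      procedure_occurrence_id = as.numeric(ids), person_id = as.numeric(ids),
      procedure_concept_id = 4300001, procedure_date = index_date,
      visit_occurrence_id = as.numeric(ids))
  )
}

# one source report row in the interchange layout
tiny_report <- function(report_id = "RPT000001", person = 1,
                        study_date = as.Date("2015-03-02"),
                        study_type = "full-night", form_version = 3,
                        fields = list(AHI_TOTAL = 32.1)) {
  tibble::tibble(
    report_id = report_id,
    source_person_id = sprintf("SRC%06d", person),
    study_date = study_date, study_type = study_type,
    form_version = as.integer(form_version),
    order_reference = "ORD000001",
    fields = list(fields))
}
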