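# CDM v5.3.1 clinical tables used by the PSG conversion, as plain tibbles in a
# named list ("cdm_bundle"). The delimited file layout written by write_cdm()
# is the interchange contract; OBSERVATION_PERIOD is carried because the
# cohort filters (lookback, time-at-risk) are defined on it.

# Field concept denoting "procedure_occurrence.procedure_occurrence_id", the
# filler for modifier_of_field_concept_id / obs_event_field_concept_id per the
# oncology-extension linkage convention. Configurable at load time.
FIELD_CONCEPT_PROCEDURE <- 1147082

cdm_table_spec <- function() {
  list(
    person = c("person_id", "gender_concept_id", "year_of_birth",
               "person_source_value"),
    observation_period = c("observation_period_id", "person_id",
                           "observation_period_start_date",
                           "observation_period_end_date"),
    visit_occurrence = c("visit_occurrence_id", "person_id",
                         "visit_concept_id", "visit_start_date",
                         "visit_end_date"),
    procedure_occurrence = c("procedure_occurrence_id", "person_id",
                             "procedure_concept_id", "procedure_date",
                             "visit_occurrence_id"),
    measurement = c("measurement_id", "person_id", "measurement_concept_id",
                    "measurement_date", "value_as_number", "unit_concept_id",
                    "visit_occurrence_id", "measurement_source_value",
                    "modifier_of_event_id", "modifier_of_field_concept_id"),
    observation = c("observation_id", "person_id", "observation_concept_id",
                    "observation_date", "value_as_number",
                    "visit_occurrence_id", "observation_source_value",
                    "observation_event_id", "obs_event_field_concept_id"),
    condition_occurrence = c("condition_occurrence_id", "person_id",
                             "condition_concept_id", "condition_start_date",
                             "condition_end_date", "condition_source_value"),
    drug_era = c("drug_era_id", "person_id", "drug_concept_id",
                 "drug_era_start_date", "drug_era_end_date",
                 "drug_source_value")
  )
}

empty_cdm_table <- function(table) {
  cols <- cdm_table_spec()[[table]]
  out <- purrr::map(cols, function(col) {
    if (grepl("date$", col)) as.Date(character(0))
    else if (grepl("source_value$", col)) character(0)
    else numeric(0)
  })
  names(out) <- cols
  tibble::as_tibble(out)
}

#' Construct a CDM bundle
#'
#' Bundles the clinical tables into a single object; omitted tables start
#' empty. The `etl_ledger` component records report ids already loaded, which
#' is what makes [transform_and_load()] idempotent.
#'
#' @param ... Named tibbles among `person`, `observation_period`,
#'   `visit_occurrence`, `procedure_occurrence`, `measurement`, `observation`,
#'   `condition_occurrence`, `drug_era`.
#' @param etl_ledger Tibble with column `report_id` (default empty).
#' @return A list of class `cdm_bundle`.
#' @export
cdm_bundle <- function(..., etl_ledger = NULL) {
  supplied <- list(...)
  unknown <- setdiff(names(supplied), names(cdm_table_spec()))
  if (length(unknown)) {
    abort_sleepcdm(paste0("unknown CDM table(s): ",
                          paste(unknown, collapse = ", ")),
                   "sleepcdm_schema_error")
  }
  bundle <- purrr::imap(cdm_table_spec(), function(cols, tab) {
    x <- supplied[[tab]] %||% empty_cdm_table(tab)
    miss <- setdiff(cols, names(x))
    if (length(miss)) {
      abort_sleepcdm(paste0("table '", tab, "' missing required column(s): ",
                            paste(miss, collapse = ", ")),
                     "sleepcdm_schema_error")
    }
    tibble::as_tibble(x)
  })
  bundle$etl_ledger <- etl_ledger %||% tibble::tibble(report_id = character(0))
  class(bundle) <- "cdm_bundle"
  bundle
}

#' Read / write a CDM bundle as delimited files
#'
#' One upper-case CSV per table (`PERSON.csv`, ...), v5.3.1 column names,
#' ISO-8601 dates. The write/read pair is the identity on values and row
#' counts. The ETL report ledger travels alongside as `ETL_LEDGER.csv`.
#'
#' @param bundle A `cdm_bundle`.
#' @param dir Directory of delimited tables.
#' @return `read_cdm()` a `cdm_bundle`; `write_cdm()` `dir`, invisibly.
#' @export
write_cdm <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cdm_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tab in names(cdm_table_spec())) {
    readr::write_csv(bundle[[tab]], file.path(dir, paste0(toupper(tab), ".csv")),
                     na = "")
  }
  readr::write_csv(bundle$etl_ledger, file.path(dir, "ETL_LEDGER.csv"), na = "")
  invisible(dir)
}

#' @rdname write_cdm
#' @export
read_cdm <- function(dir) {
  spec <- cdm_table_spec()
  tables <- purrr::imap(spec, function(cols, tab) {
    path <- file.path(dir, paste0(toupper(tab), ".csv"))
    if (!file.exists(path)) return(empty_cdm_table(tab))
    x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           .default = readr::col_guess()))
    miss <- setdiff(cols, names(x))
    if (length(miss)) {
      abort_sleepcdm(paste0("file ", basename(path),
                            " missing required column(s): ",
                            paste(miss, collapse = ", ")),
                     "sleepcdm_schema_error")
    }
    if (nrow(x) == 0) return(empty_cdm_table(tab))
    # empty columns read as logical NA; coerce to the schema types
    for (col in cols) {
      if (is.logical(x[[col]])) {
        x[[col]] <- if (grepl("date$", col)) as.Date(x[[col]])
        else if (grepl("source_value$", col)) as.character(x[[col]])
        else as.numeric(x[[col]])
      }
    }
    x
  })
  ledger_path <- file.path(dir, "ETL_LEDGER.csv")
  ledger <- if (file.exists(ledger_path)) {
    lx <- readr::read_csv(ledger_path, show_col_types = FALSE, progress = FALSE)
    if (nrow(lx)) dplyr::mutate(lx, report_id = as.character(.data$report_id))
    else tibble::tibble(report_id = character(0))
  } else NULL
  do.call(cdm_bundle, c(tables, list(etl_ledger = ledger)))
}

#' Validate referential integrity of a CDM bundle
#'
#' Pure check of every foreign key and event-linkage reference: persons behind
#' visits, procedures, measurements, observations, conditions, drug eras and
#' observation periods; visit references; `modifier_of_event_id` /
#' `observation_event_id` resolving to an existing procedure row with the
#' procedure field concept; date ordering; plausible birth years. Violations
#' are data, not exceptions.
#'
#' @param bundle A `cdm_bundle`.
#' @param field_concept Expected value of the linkage field concept
#'   (default `FIELD_CONCEPT_PROCEDURE`).
#' @return Tibble with columns `table`, `row_id`, `field`, `problem`;
#'   zero rows iff the bundle is internally consistent.
#' @export
validate_referential_integrity <- function(bundle,
                                           field_concept = FIELD_CONCEPT_PROCEDURE) {
  stopifnot(inherits(bundle, "cdm_bundle"))
  out <- list()
  bad <- function(table, row_id, field, problem) {
    if (length(row_id)) {
      out[[length(out) + 1]] <<- tibble::tibble(
        table = table, row_id = as.numeric(row_id), field = field,
        problem = problem)
    }
  }
  persons <- bundle$person$person_id
  if (anyDuplicated(persons)) {
    bad("person", persons[duplicated(persons)], "person_id", "duplicate person_id")
  }
  yob <- bundle$person$year_of_birth
  implausible <- !is.na(yob) &
    (yob < 1900 | yob > as.integer(format(Sys.Date(), "%Y")))
  bad("person", bundle$person$person_id[implausible], "year_of_birth",
      "implausible year_of_birth")

  fk_person <- function(tab, id_col) {
    x <- bundle[[tab]]
    miss <- !x$person_id %in% persons
    bad(tab, x[[id_col]][miss], "person_id", "person_id not in person")
  }
  fk_person("observation_period", "observation_period_id")
  fk_person("visit_occurrence", "visit_occurrence_id")
  fk_person("procedure_occurrence", "procedure_occurrence_id")
  fk_person("measurement", "measurement_id")
  fk_person("observation", "observation_id")
  fk_person("condition_occurrence", "condition_occurrence_id")
  fk_person("drug_era", "drug_era_id")

  visits <- bundle$visit_occurrence$visit_occurrence_id
  procs <- bundle$procedure_occurrence$procedure_occurrence_id

  vo <- bundle$visit_occurrence
  bad("visit_occurrence",
      vo$visit_occurrence_id[!is.na(vo$visit_start_date) &
                               !is.na(vo$visit_end_date) &
                               vo$visit_start_date > vo$visit_end_date],
      "visit_start_date", "visit_start_date after visit_end_date")

  po <- bundle$procedure_occurrence
  miss_v <- !is.na(po$visit_occurrence_id) & !po$visit_occurrence_id %in% visits
  bad("procedure_occurrence", po$procedure_occurrence_id[miss_v],
      "visit_occurrence_id", "visit_occurrence_id not in visit_occurrence")

  me <- bundle$measurement
  miss_v <- !is.na(me$visit_occurrence_id) & !me$visit_occurrence_id %in% visits
  bad("measurement", me$measurement_id[miss_v], "visit_occurrence_id",
      "visit_occurrence_id not in visit_occurrence")
  has_mod <- !is.na(me$modifier_of_event_id)
  miss_p <- has_mod & !me$modifier_of_event_id %in% procs
  bad("measurement", me$measurement_id[miss_p], "modifier_of_event_id",
      "modifier_of_event_id not in procedure_occurrence")
  bad_fc <- has_mod & (is.na(me$modifier_of_field_concept_id) |
                         me$modifier_of_field_concept_id != field_concept)
  bad("measurement", me$measurement_id[bad_fc], "modifier_of_field_concept_id",
      "linkage set but field concept does not identify procedure_occurrence")

  ob <- bundle$observation
  has_ev <- !is.na(ob$observation_event_id)
  miss_p <- has_ev & !ob$observation_event_id %in% procs
  bad("observation", ob$observation_id[miss_p], "observation_event_id",
      "observation_event_id not in procedure_occurrence")
  bad_fc <- has_ev & (is.na(ob$obs_event_field_concept_id) |
                        ob$obs_event_field_concept_id != field_concept)
  bad("observation", ob$observation_id[bad_fc], "obs_event_field_concept_id",
      "linkage set but field concept does not identify procedure_occurrence")

  co <- bundle$condition_occurrence
  bad("condition_occurrence",
      co$condition_occurrence_id[!is.na(co$condition_start_date) &
                                   !is.na(co$condition_end_date) &
                                   co$condition_start_date > co$condition_end_date],
      "condition_start_date", "condition_start_date after condition_end_date")

  op <- bundle$observation_period
  bad("observation_period",
      op$observation_period_id[op$observation_period_start_date >
                                 op$observation_period_end_date],
      "observation_period_start_date", "period start after end")

  if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(table = character(0), row_id = numeric(0),
                   field = character(0), problem = character(0))
  }
}

#' @export
print.cdm_bundle <- function(x, ...) {
  cat("<cdm_bundle>\n")
  for (tab in names(cdm_table_spec())) {
    cat(sprintf("  %-22s %6d rows\n", tab, nrow(x[[tab]])))
  }
  cat(sprintf("  %-22s %6d reports loaded\n", "etl_ledger", nrow(x$etl_ledger)))
  invisible(x)
}
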