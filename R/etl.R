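# Extract-transform-load of versioned source PSG reports into measurement /
# observation rows linked to their ordering procedure. The source report forms
# went through ~11 revisions; each revision is a field-name dialect with its
# own unit quirks, captured as data in a form-version map.

#' Default form-version maps
#'
#' The real report dialects are unpublished, so the package ships synthetic
#' stand-in dialects, one per form version 1-11, that exercise the same
#' machinery: per-version field-name schemes plus unit quirks (body height
#' recorded in metres in versions 1-2, sleep efficiency as a 0-1 fraction in
#' versions 1-3). `factor` multiplies the raw value into the canonical
#' catalog unit.
#'
#' @param catalog A [psg_parameter_catalog()] tibble.
#' @return Tibble with columns `form_version`, `source_field`,
#'   `parameter_name`, `source_code`, `factor`.
#' @export
default_form_version_maps <- function(catalog = psg_parameter_catalog()) {
  dialect_field <- function(version, code) {
    if (version <= 2) tolower(gsub("_", ".", code))
    else if (version <= 5) code
    else if (version <= 8) paste0("psg_", tolower(code))
    else paste0("PSG.", code)
  }
  purrr::map_dfr(1:11, function(v) {
    tibble::tibble(
      form_version = v,
      source_field = vapply(catalog$source_code, dialect_field,
                            character(1), version = v, USE.NAMES = FALSE),
      parameter_name = catalog$parameter_name,
      source_code = catalog$source_code,
      factor = dplyr::case_when(
        catalog$source_code == "HT" & v <= 2 ~ 100,      # metres -> cm
        catalog$source_code == "SE_PCT" & v <= 3 ~ 100,  # fraction -> %
        TRUE ~ 1
      )
    )
  })
}

#' Extract one source report into canonical parameters
#'
#' Renames the report's raw fields to canonical catalog parameter names using
#' the map for its form version and applies unit conversions. Fields absent
#' from the report are omitted (never zero-filled); fields that the version
#' map does not know are skipped with a warning and counted.
#'
#' @param raw_record A one-row report tibble or a list with elements
#'   `report_id`, `form_version` and `fields` (named list of raw values).
#' @param version_maps Map tibble from [default_form_version_maps()].
#' @return Tibble with columns `parameter_name`, `source_code`, `value`;
#'   attribute `skipped_fields` holds the unmappable field names.
#' @export
extract_report <- function(raw_record, version_maps = default_form_version_maps()) {
  fields <- raw_record$fields
  if (is.data.frame(raw_record)) fields <- raw_record$fields[[1]]
  version <- as.integer(raw_record$form_version)
  vmap <- dplyr::filter(version_maps, .data$form_version == version)
  if (nrow(vmap) == 0) {
    abort_sleepcdm(paste0("unknown form_version: ", version),
                   "sleepcdm_unknown_version")
  }
  fields <- fields[!vapply(fields, function(x) is.na(x) || is.null(x), logical(1))]
  idx <- match(names(fields), vmap$source_field)
  skipped <- names(fields)[is.na(idx)]
  if (length(skipped)) {
    rlang::warn(paste0("report ", raw_record$report_id[[1]], ": skipped ",
                       length(skipped), " unmappable field(s): ",
                       paste(skipped, collapse = ", ")))
  }
  keep <- !is.na(idx)
  out <- tibble::tibble(
    parameter_name = vmap$parameter_name[idx[keep]],
    source_code = vmap$source_code[idx[keep]],
    value = as.numeric(unlist(fields[keep], use.names = FALSE)) *
      vmap$factor[idx[keep]]
  )
  attr(out, "skipped_fields") <- skipped
  out
}

#' Link source reports to their ordering procedures
#'
#' Each report is matched to an existing procedure row of the same person
#' (via `person_source_value`) and study-type concept whose `procedure_date`
#' lies within `window` days of the study date. The nearest date wins; ties
#' break to the earliest date, then the lowest `procedure_occurrence_id`.
#' Reports with no candidate are returned unlinked with a reason, and are
#' quarantined by [transform_and_load()].
#'
#' @param reports Source report tibble (see [generate_sleep_ehr()] for the
#'   layout).
#' @param cdm A `cdm_bundle` holding `person` and `procedure_occurrence`.
#' @param window Matching half-width in days (default 1: the order may
#'   precede the overnight study by a day).
#' @return Tibble `report_id`, `person_id`, `procedure_occurrence_id`,
#'   `visit_occurrence_id`, `reason` (`NA` when linked).
#' @export
link_to_procedure <- function(reports, cdm, window = 1) {
  stopifnot(inherits(cdm, "cdm_bundle"))
  type_ids <- study_type_concept_ids()
  persons <- dplyr::select(cdm$person, "person_id", "person_source_value")
  reps <- reports |>
    dplyr::left_join(persons, by = c(source_person_id = "person_source_value")) |>
    dplyr::mutate(type_concept = type_ids[.data$study_type])

  cand <- reps |>
    dplyr::select("report_id", "person_id", "study_date", "type_concept") |>
    dplyr::inner_join(cdm$procedure_occurrence,
                      by = c("person_id", type_concept = "procedure_concept_id"),
                      relationship = "many-to-many") |>
    dplyr::mutate(dist = abs(as.numeric(.data$procedure_date - .data$study_date))) |>
    dplyr::filter(.data$dist <= window) |>
    dplyr::arrange(.data$report_id, .data$dist, .data$procedure_date,
                   .data$procedure_occurrence_id) |>
    dplyr::distinct(.data$report_id, .keep_all = TRUE)

  reps |>
    dplyr::select("report_id", "person_id") |>
    dplyr::left_join(dplyr::select(cand, "report_id", "procedure_occurrence_id",
                                   "visit_occurrence_id"),
                     by = "report_id") |>
    dplyr::mutate(reason = dplyr::case_when(
      is.na(.data$person_id) ~ "unknown person",
      is.na(.data$procedure_occurrence_id) ~ "no matching order",
      TRUE ~ NA_character_
    ))
}

#' Transform and load source reports into the CDM
#'
#' Runs the full load for a batch of reports: skips reports already in the
#' bundle's ETL ledger (idempotence), links the rest to procedures, extracts
#' and standardizes their fields, and appends one measurement row per
#' populated Measurement-domain parameter and one observation row per
#' Observation-domain parameter (Waist/hip ratio), each carrying the
#' oncology-extension linkage fields back to its procedure. Unlinked reports
#' are quarantined, never silently dropped.
#'
#' @param reports Source report tibble.
#' @param vocabulary A `psg_vocabulary`.
#' @param cdm A `cdm_bundle`; returned updated.
#' @param version_maps Form-version map (default
#'   [default_form_version_maps()] on the bundle's catalog).
#' @param window Linkage window in days, passed to [link_to_procedure()].
#' @return List with `cdm` (updated bundle), `summary` (one-row tibble of
#'   per-stage counts), and `quarantined` (report ids + reasons).
#' @export
transform_and_load <- function(reports, vocabulary, cdm,
                               version_maps = NULL, window = 1) {
  stopifnot(inherits(vocabulary, "psg_vocabulary"), inherits(cdm, "cdm_bundle"))
  version_maps <- version_maps %||% default_form_version_maps(vocabulary$catalog)

  already <- reports$report_id %in% cdm$etl_ledger$report_id
  new_reports <- reports[!already, , drop = FALSE]

  links <- link_to_procedure(new_reports, cdm, window = window)
  quarantined <- dplyr::filter(links, !is.na(.data$reason))
  linked <- dplyr::filter(links, is.na(.data$reason))

  load_reports <- dplyr::inner_join(new_reports, linked, by = "report_id")

  # vectorized extraction over the whole batch; semantics identical to
  # mapping extract_report() over every record
  bad_version <- setdiff(unique(load_reports$form_version),
                         unique(version_maps$form_version))
  if (length(bad_version)) {
    abort_sleepcdm(paste0("unknown form_version: ",
                          paste(bad_version, collapse = ", ")),
                   "sleepcdm_unknown_version")
  }
  long <- load_reports |>
    dplyr::select("report_id", "form_version", "person_id",
                  date = "study_date", "procedure_occurrence_id",
                  "visit_occurrence_id", "fields") |>
    dplyr::mutate(source_field = purrr::map(.data$fields, names),
                  raw = purrr::map(.data$fields,
                                   ~ as.numeric(unlist(.x, use.names = FALSE)))) |>
    dplyr::select(-"fields") |>
    tidyr::unnest(c("source_field", "raw")) |>
    dplyr::filter(!is.na(.data$raw))
  long <- dplyr::left_join(long, version_maps,
                           by = c("form_version", "source_field"))
  n_skipped_fields <- sum(is.na(long$parameter_name))
  rows <- long |>
    dplyr::filter(!is.na(.data$parameter_name)) |>
    dplyr::mutate(value = .data$raw * .data$factor) |>
    dplyr::select("parameter_name", "source_code", "value", "person_id",
                  "date", "procedure_occurrence_id", "visit_occurrence_id")

  n_meas <- 0L; n_obs <- 0L
  if (nrow(rows)) {
    cat2 <- vocabulary$catalog
    rows <- dplyr::left_join(
      rows,
      dplyr::select(cat2, "source_code", "standard_concept_id", "domain"),
      by = "source_code")
    if (anyNA(rows$standard_concept_id)) {
      bad <- unique(rows$source_code[is.na(rows$standard_concept_id)])
      abort_sleepcdm(paste0("unmapped source code(s) reached load: ",
                            paste(bad, collapse = ", ")),
                     "sleepcdm_unmapped_code", codes = bad)
    }
    m <- dplyr::filter(rows, .data$domain == "Measurement")
    o <- dplyr::filter(rows, .data$domain == "Observation")
    next_id <- function(ids) if (length(ids)) max(ids) + 1 else 1
    if (nrow(m)) {
      cdm$measurement <- dplyr::bind_rows(cdm$measurement, tibble::tibble(
        measurement_id = next_id(cdm$measurement$measurement_id) +
          seq_len(nrow(m)) - 1,
        person_id = m$person_id,
        measurement_concept_id = m$standard_concept_id,
        measurement_date = m$date,
        value_as_number = m$value,
        unit_concept_id = 0,
        visit_occurrence_id = m$visit_occurrence_id,
        measurement_source_value = m$source_code,
        modifier_of_event_id = m$procedure_occurrence_id,
        modifier_of_field_concept_id = FIELD_CONCEPT_PROCEDURE
      ))
      n_meas <- nrow(m)
    }
    if (nrow(o)) {
      cdm$observation <- dplyr::bind_rows(cdm$observation, tibble::tibble(
        observation_id = next_id(cdm$observation$observation_id) +
          seq_len(nrow(o)) - 1,
        person_id = o$person_id,
        observation_concept_id = o$standard_concept_id,
        observation_date = o$date,
        value_as_number = o$value,
        visit_occurrence_id = o$visit_occurrence_id,
        observation_source_value = o$source_code,
        observation_event_id = o$procedure_occurrence_id,
        obs_event_field_concept_id = FIELD_CONCEPT_PROCEDURE
      ))
      n_obs <- nrow(o)
    }
  }

  cdm$etl_ledger <- dplyr::bind_rows(
    cdm$etl_ledger,
    tibble::tibble(report_id = as.character(load_reports$report_id)))

  list(
    cdm = cdm,
    summary = tibble::tibble(
      reports_in = nrow(reports),
      already_loaded = sum(already),
      quarantined = nrow(quarantined),
      fields_skipped = n_skipped_fields,
      measurements_added = n_meas,
      observations_added = n_obs
    ),
    quarantined = dplyr::select(quarantined, "report_id", "reason")
  )
}
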