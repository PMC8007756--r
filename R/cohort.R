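# Target and outcome cohorts for the patient-level prediction feasibility
# test, with an attrition ledger that mirrors the usual inclusion flowchart:
# full-night tests, adults, sufficient pre-index observation, full
# time-at-risk, no prior outcome, one test per person.

#' Cohort definition
#'
#' @param study_type Study-type filter (default `"full-night"`).
#' @param min_age Minimum age in years at the test (default 18).
#' @param min_lookback Required pre-index observation in days; the
#'   feasibility settings use 30, 90 or 180 (default 90).
#' @param tar_start,tar_end Time-at-risk window in days after the index test
#'   (defaults 1 and 1095, both inclusive).
#' @param require_full_tar Drop subjects whose observation ends before
#'   `index + 1094` days (default `TRUE`).
#' @param exclude_prior_outcome Drop subjects with an outcome on or before
#'   the index date (default `TRUE`).
#' @param one_per_person Keep only the earliest qualifying test per person
#'   (default `TRUE`; avoids within-person label leakage).
#' @return A list of class `cohort_definition`.
#' @export
cohort_definition <- function(study_type = "full-night", min_age = 18,
                              min_lookback = 90, tar_start = 1,
                              tar_end = 1095, require_full_tar = TRUE,
                              exclude_prior_outcome = TRUE,
                              one_per_person = TRUE) {
  if (tar_start < 1 || tar_end <= tar_start) {
    abort_sleepcdm("time-at-risk must satisfy 1 <= start < end",
                   "sleepcdm_config_error")
  }
  structure(list(study_type = study_type, min_age = min_age,
                 min_lookback = min_lookback, tar_start = tar_start,
                 tar_end = tar_end, require_full_tar = require_full_tar,
                 exclude_prior_outcome = exclude_prior_outcome,
                 one_per_person = one_per_person),
            class = "cohort_definition")
}

#' Outcome definition
#'
#' Any occurrence of a code starting with one of the ICD-10 prefixes
#' qualifies, with no frequency constraint.
#'
#' @param icd10_codes Character vector of ICD-10 codes or prefixes
#'   (default [default_outcome_codes()]).
#' @return A list of class `outcome_definition`.
#' @export
outcome_definition <- function(icd10_codes = default_outcome_codes()) {
  ok <- grepl("^[A-Z][0-9]{2}", icd10_codes)
  if (!all(ok)) {
    abort_sleepcdm(paste0("syntactically invalid ICD-10 code(s): ",
                          paste(icd10_codes[!ok], collapse = ", ")),
                   "sleepcdm_config_error")
  }
  structure(list(icd10_codes = icd10_codes), class = "outcome_definition")
}

matches_outcome <- function(codes, outcome) {
  pattern <- paste0("^(", paste(gsub("\\.", "\\\\.", outcome$icd10_codes),
                                collapse = "|"), ")")
  grepl(pattern, codes)
}

#' Build the target cohort with its attrition ledger
#'
#' Applies the inclusion filters sequentially, recording the count after each
#' step: study type, age at index, pre-index observation of at least
#' `min_lookback` days, full time-at-risk (observation end at least
#' `index + tar_end - 1` days), no outcome on or before index, and one test
#' per person (earliest). The ledger is monotone non-increasing and its first
#' count is the study-type-filtered total.
#'
#' @param cdm A `cdm_bundle`.
#' @param definition A [cohort_definition()].
#' @param outcome An [outcome_definition()] (used by the prior-outcome step).
#' @return List with `entries` (tibble `person_id`, `index_date`,
#'   `tar_start`, `tar_end`) and `attrition` (tibble `step`, `description`,
#'   `n_remaining`, `n_removed`), classed `psg_cohort`.
#' @export
build_target_cohort <- function(cdm, definition = cohort_definition(),
                                outcome = outcome_definition()) {
  stopifnot(inherits(cdm, "cdm_bundle"),
            inherits(definition, "cohort_definition"))
  steps <- list()
  log_step <- function(desc, n) {
    steps[[length(steps) + 1]] <<- tibble::tibble(
      step = length(steps) + 1L, description = desc, n_remaining = n)
  }
  type_id <- study_type_concept_ids()[[definition$study_type]]
  cand <- cdm$procedure_occurrence |>
    dplyr::filter(.data$procedure_concept_id == type_id) |>
    dplyr::transmute(person_id = .data$person_id,
                     index_date = .data$procedure_date)
  log_step(paste0(definition$study_type, " sleep tests"), nrow(cand))

  cand <- cand |>
    dplyr::left_join(dplyr::select(cdm$person, "person_id", "year_of_birth"),
                     by = "person_id") |>
    dplyr::mutate(age = as.integer(format(.data$index_date, "%Y")) -
                    .data$year_of_birth) |>
    dplyr::filter(.data$age >= definition$min_age)
  log_step(paste0("age >= ", definition$min_age), nrow(cand))

  op <- dplyr::select(cdm$observation_period, "person_id",
                      op_start = "observation_period_start_date",
                      op_end = "observation_period_end_date")
  cand <- cand |>
    dplyr::left_join(op, by = "person_id",
                     relationship = "many-to-many") |>
    dplyr::filter(!is.na(.data$op_start),
                  .data$op_start <= .data$index_date - definition$min_lookback,
                  .data$op_end >= .data$index_date) |>
    dplyr::distinct(.data$person_id, .data$index_date, .keep_all = TRUE)
  log_step(paste0("lookback >= ", definition$min_lookback, " days"),
           nrow(cand))

  if (definition$require_full_tar) {
    cand <- dplyr::filter(
      cand, .data$op_end >= .data$index_date + definition$tar_end - 1)
  }
  log_step(paste0("full time-at-risk (", definition$tar_end - 1, " days)"),
           nrow(cand))

  if (definition$exclude_prior_outcome && nrow(cdm$condition_occurrence)) {
    prior <- cdm$condition_occurrence |>
      dplyr::filter(matches_outcome(.data$condition_source_value, outcome)) |>
      dplyr::select("person_id", outcome_date = "condition_start_date")
    cand <- cand |>
      dplyr::left_join(prior, by = "person_id",
                       relationship = "many-to-many") |>
      dplyr::group_by(.data$person_id, .data$index_date) |>
      dplyr::filter(all(is.na(.data$outcome_date) |
                          .data$outcome_date > .data$index_date)) |>
      dplyr::ungroup() |>
      dplyr::distinct(.data$person_id, .data$index_date, .keep_all = TRUE) |>
      dplyr::select(-"outcome_date")
  }
  log_step("no prior outcome", nrow(cand))

  if (definition$one_per_person) {
    cand <- cand |>
      dplyr::arrange(.data$person_id, .data$index_date) |>
      dplyr::distinct(.data$person_id, .keep_all = TRUE)
  }
  log_step("one test per person (earliest)", nrow(cand))

  entries <- cand |>
    dplyr::transmute(
      person_id = .data$person_id, index_date = .data$index_date,
      age = .data$age,
      tar_start = .data$index_date + definition$tar_start,
      tar_end = .data$index_date + definition$tar_end)
  attrition <- dplyr::bind_rows(steps) |>
    dplyr::mutate(n_removed = dplyr::lag(.data$n_remaining,
                                         default = dplyr::first(.data$n_remaining)) -
                    .data$n_remaining)
  structure(list(entries = entries, attrition = attrition,
                 definition = definition),
            class = "psg_cohort")
}

#' Label cohort entries with the outcome
#'
#' Label 1 iff any qualifying condition occurrence is dated within the
#' (inclusive) time-at-risk window.
#'
#' @param entries Cohort entry tibble (from [build_target_cohort()]'s
#'   `entries`, or a `psg_cohort`).
#' @param outcome An [outcome_definition()].
#' @param conditions Condition-occurrence tibble.
#' @return The entries tibble with a `label` column (0/1); attribute
#'   `outcome_rate` is `100 * positives / n`, rounded half-up to two
#'   decimals.
#' @examples
#' # 639 subjects of whom 71 experience the outcome inside time-at-risk
#' entries <- tibble::tibble(
#'   person_id = 1:639, index_date = as.Date("2015-01-01"),
#'   tar_start = index_date + 1, tar_end = index_date + 1095)
#' conditions <- tibble::tibble(
#'   person_id = 1:71, condition_source_value = "I10",
#'   condition_start_date = as.Date("2015-01-01") + 400)
#' labelled <- label_outcomes(entries, outcome_definition(), conditions)
#' attr(labelled, "outcome_rate")  # 11.11
#' @export
label_outcomes <- function(entries, outcome, conditions) {
  stopifnot(inherits(outcome, "outcome_definition"))
  if (inherits(entries, "psg_cohort")) entries <- entries$entries
  if (nrow(entries) == 0) {
    out <- dplyr::mutate(entries, label = integer(0))
    attr(out, "outcome_rate") <- NA_real_
    return(out)
  }
  qual <- conditions |>
    dplyr::filter(matches_outcome(.data$condition_source_value, outcome)) |>
    dplyr::select("person_id", outcome_date = "condition_start_date")
  hits <- entries |>
    dplyr::inner_join(qual, by = "person_id",
                      relationship = "many-to-many") |>
    dplyr::filter(.data$outcome_date >= .data$tar_start,
                  .data$outcome_date <= .data$tar_end) |>
    dplyr::distinct(.data$person_id, .data$index_date)
  out <- entries |>
    dplyr::mutate(label = as.integer(paste(.data$person_id, .data$index_date) %in%
                                       paste(hits$person_id, hits$index_date)))
  attr(out, "outcome_rate") <- round_half_up(100 * sum(out$label) / nrow(out), 2)
  out
}

#' Plot an attrition ledger
#'
#' @param cohort A `psg_cohort` (or its `attrition` tibble).
#' @return A ggplot step chart of remaining subjects per inclusion step.
#' @export
plot_attrition <- function(cohort) {
  att <- if (inherits(cohort, "psg_cohort")) cohort$attrition else cohort
  ggplot2::ggplot(att, ggplot2::aes(
    x = stats::reorder(.data$description, .data$step),
    y = .data$n_remaining)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_remaining), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "subjects remaining") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
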