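# Post-load data-quality rule engine. The rules the original cleaning step
# used are not public, so the default set below is a declared stand-in built
# from the catalog's value kinds; rules are data (a tibble / CSV), fully
# replaceable by site-specific configuration.

#' Default cleaning rule set
#'
#' Derives one rule per parameter from its value kind: percentage parameters
#' are bounded to \[0, 100\]; oxygen-saturation parameters to (0, 100\];
#' indices, durations, counts, scores, grades, pressures and anthropometrics
#' must be non-negative; BMI is restricted to (10, 100); and a cross-field
#' rule removes total-sleep-time values exceeding time in bed within the same
#' study.
#'
#' @param catalog A [psg_parameter_catalog()] tibble (empty catalog gives an
#'   empty rule set).
#' @param action `"remove"` (default) or `"flag"` applied to every rule.
#' @return A rule tibble: `rule_id`, `parameter_name`, `kind`, `lower`,
#'   `upper`, `lower_open`, `upper_open`, `action`.
#' @export
default_rule_set <- function(catalog = psg_parameter_catalog(),
                             action = "remove") {
  if (nrow(catalog) == 0) {
    return(tibble::tibble(rule_id = character(0), parameter_name = character(0),
                          kind = character(0), lower = numeric(0),
                          upper = numeric(0), lower_open = logical(0),
                          upper_open = logical(0), action = character(0)))
  }
  per_param <- catalog |>
    dplyr::transmute(
      parameter_name = .data$parameter_name,
      kind = dplyr::case_when(
        .data$value_kind == "percentage" ~ "percentage-bounds",
        .data$value_kind == "saturation" ~ "range",
        .data$value_kind == "bmi" ~ "range",
        TRUE ~ "non-negative"
      ),
      lower = dplyr::case_when(
        .data$value_kind == "bmi" ~ 10,
        TRUE ~ 0
      ),
      upper = dplyr::case_when(
        .data$value_kind %in% c("percentage", "saturation") ~ 100,
        .data$value_kind == "bmi" ~ 100,
        TRUE ~ Inf
      ),
      lower_open = .data$value_kind %in% c("saturation", "bmi"),
      upper_open = .data$value_kind == "bmi"
    ) |>
    dplyr::mutate(
      rule_id = sprintf("R%03d", dplyr::row_number()),
      action = action
    )
  cross <- tibble::tibble(
    rule_id = sprintf("R%03d", nrow(per_param) + 1L),
    parameter_name = "Total sleep time (TST) (min)",
    kind = "cross-field",
    lower = NA_real_, upper = NA_real_,
    lower_open = FALSE, upper_open = FALSE,
    action = action
  )
  dplyr::bind_rows(
    dplyr::select(per_param, "rule_id", "parameter_name", "kind", "lower",
                  "upper", "lower_open", "upper_open", "action"),
    cross)
}

#' Read a cleaning-rule configuration
#'
#' @param path CSV file with the columns of [default_rule_set()].
#' @return A rule tibble.
#' @export
read_cleaning_rules <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

#' Apply cleaning rules to loaded measurements
#'
#' Partitions the measurement table into kept and removed rows. A row is
#' removed by the first rule (in rule order) it violates, and the per-rule
#' ledger counts sum exactly to the removed total. Re-applying the rules to
#' the kept rows removes nothing (idempotence). The cross-field rule compares
#' total sleep time against time in bed within the rows linked to the same
#' procedure.
#'
#' @param measurements CDM measurement tibble (as loaded by
#'   [transform_and_load()]; parameters identified by
#'   `measurement_source_value`).
#' @param rules Rule tibble, e.g. [default_rule_set()].
#' @param catalog Catalog used to map source codes to parameter names.
#' @return List with `kept`, `removed` (both measurement tibbles; `removed`
#'   gains a `rule_id` column) and `ledger` (`rule_id`, `n_removed`).
#' @export
apply_rules <- function(measurements, rules,
                        catalog = psg_parameter_catalog()) {
  known <- c(catalog$parameter_name, NA_character_)
  bad <- setdiff(unique(rules$parameter_name), known)
  if (length(bad)) {
    abort_sleepcdm(paste0("rule(s) reference unknown parameter(s): ",
                          paste(bad, collapse = "; ")),
                   "sleepcdm_config_error")
  }
  if (nrow(measurements) == 0) {
    return(list(kept = measurements,
                removed = dplyr::mutate(measurements, rule_id = character(0)),
                ledger = tibble::tibble(rule_id = rules$rule_id, n_removed = 0L)))
  }
  param_of <- catalog$parameter_name[match(measurements$measurement_source_value,
                                           catalog$source_code)]
  hit <- rep(NA_character_, nrow(measurements))

  tib_code <- catalog$source_code[
    catalog$parameter_name == "Total time analyzed (Time In bed, TIB) (min)"]
  tst_code <- catalog$source_code[
    catalog$parameter_name == "Total sleep time (TST) (min)"]

  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    if (r$kind == "cross-field") {
      # TST <= TIB within the same linked procedure
      tib <- measurements |>
        dplyr::filter(.data$measurement_source_value %in% tib_code) |>
        dplyr::select("modifier_of_event_id", tib = "value_as_number")
      cand <- which(param_of == r$parameter_name & is.na(hit))
      if (length(cand) && nrow(tib)) {
        tib_val <- tib$tib[match(measurements$modifier_of_event_id[cand],
                                 tib$modifier_of_event_id)]
        viol <- !is.na(tib_val) &
          measurements$value_as_number[cand] > tib_val
        hit[cand[viol]] <- r$rule_id
      }
    } else {
      cand <- which(param_of == r$parameter_name & is.na(hit))
      if (!length(cand)) next
      val <- measurements$value_as_number[cand]
      low_bad <- if (isTRUE(r$lower_open)) val <= r$lower else val < r$lower
      up_bad <- if (isTRUE(r$upper_open)) val >= r$upper else val > r$upper
      viol <- is.na(val) | low_bad | up_bad
      hit[cand[viol]] <- r$rule_id
    }
  }

  act <- stats::setNames(rules$action, rules$rule_id)
  removed_idx <- !is.na(hit) & act[hit] == "remove"
  flagged_idx <- !is.na(hit) & act[hit] == "flag"

  kept <- measurements[!removed_idx, , drop = FALSE]
  if (any(flagged_idx)) {
    kept$qc_flag <- NA_character_
    kept$qc_flag[match(which(flagged_idx), which(!removed_idx))] <-
      hit[flagged_idx]
  }
  removed <- dplyr::mutate(measurements[removed_idx, , drop = FALSE],
                           rule_id = hit[removed_idx])
  ledger <- tibble::tibble(rule_id = rules$rule_id) |>
    dplyr::left_join(dplyr::count(removed, .data$rule_id, name = "n_removed"),
                     by = "rule_id") |>
    dplyr::mutate(n_removed = dplyr::coalesce(.data$n_removed, 0L))
  list(kept = kept, removed = removed, ledger = ledger)
}
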