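# Windowed covariate construction over the CDM, mirroring the two feasibility
# settings: "all" (every CDM family plus the PSG parameters) and "psg_only"
# (gender, age group, PSG parameters). All windows end at the index date; no
# covariate may use data after day 0.

#' Covariate settings
#'
#' @param setting `"all"` or `"psg_only"`.
#' @param windows List of `c(start, end)` day-offset pairs; every window must
#'   end at day 0 (defaults: `[-7,0]`, `[-30,0]`, `[-180,0]`, inclusive).
#' @return A list of class `covariate_settings`.
#' @export
covariate_settings <- function(setting = c("all", "psg_only"),
                               windows = list(c(-7, 0), c(-30, 0),
                                              c(-180, 0))) {
  setting <- match.arg(setting)
  ends <- vapply(windows, function(w) w[2], numeric(1))
  if (any(ends != 0)) {
    abort_sleepcdm("every covariate window must end at day 0 (the index date)",
                   "sleepcdm_config_error")
  }
  structure(list(setting = setting, windows = windows),
            class = "covariate_settings")
}

#' Extract a covariate matrix for a labelled cohort
#'
#' Builds one row per cohort entry. Value covariates (PSG parameters,
#' laboratory measurements, observations) take the most recent in-window
#' value; occurrence covariates (condition groups by 3-character ICD-10
#' prefix, procedures, visit counts) are in-window totals; drug-era group
#' covariates are overlap indicators; the comorbidity scores (Charlson,
#' CHA2DS2-VASc, DCSI) are computed from all conditions on or before index.
#' Strictly nothing after day 0 is touched. Columns with zero variance are
#' dropped with a message.
#'
#' @param entries Labelled cohort entries (need `person_id`, `index_date`,
#'   `age`; `label` is carried through if present).
#' @param cdm A `cdm_bundle` (after the PSG load).
#' @param vocabulary A `psg_vocabulary`, used to tell PSG parameter concepts
#'   from other measurements.
#' @param settings A [covariate_settings()].
#' @return A list of class `psg_covariates`: `x` (numeric matrix,
#'   rows = entries), `entries`, `setting`, `dropped` (names of zero-variance
#'   columns).
#' @export
extract_covariates <- function(entries, cdm, vocabulary,
                               settings = covariate_settings("all")) {
  stopifnot(inherits(cdm, "cdm_bundle"), inherits(vocabulary, "psg_vocabulary"),
            inherits(settings, "covariate_settings"))
  n <- nrow(entries)
  ent <- entries |>
    dplyr::mutate(.entry = dplyr::row_number()) |>
    dplyr::select(".entry", "person_id", "index_date", "age")

  blocks <- list()

  # gender + 5-year age group
  gender <- cdm$person$gender_concept_id[match(ent$person_id,
                                               cdm$person$person_id)]
  blocks$demo <- {
    grp <- pmin(ent$age %/% 5, 19) * 5
    levs <- sort(unique(grp))
    age_cols <- matrix(vapply(levs, function(l) as.numeric(grp == l),
                              numeric(n)),
                       nrow = n,
                       dimnames = list(NULL, paste0("age group: ", levs, "-",
                                                    levs + 4)))
    cbind(`gender: male` = as.numeric(gender == 8507), age_cols)
  }

  psg_concepts <- vocabulary$catalog$standard_concept_id
  psg_names <- stats::setNames(vocabulary$catalog$parameter_name,
                               as.character(psg_concepts))

  value_block <- function(rows, id_col, val_col, date_col, name_of, family, w) {
    joined <- rows |>
      dplyr::inner_join(ent, by = "person_id",
                        relationship = "many-to-many") |>
      dplyr::mutate(day = as.numeric(.data[[date_col]] - .data$index_date)) |>
      dplyr::filter(.data$day >= w[1], .data$day <= 0) |>
      # most recent value in-window per (entry, concept)
      dplyr::arrange(dplyr::desc(.data$day)) |>
      dplyr::distinct(.data$.entry, .data[[id_col]], .keep_all = TRUE)
    if (nrow(joined) == 0) return(NULL)
    wide <- joined |>
      dplyr::mutate(col = paste0(family, " during day ", w[1],
                                 " through 0 days relative to index: ",
                                 name_of(.data[[id_col]]))) |>
      dplyr::select(".entry", "col", val = dplyr::all_of(val_col)) |>
      tidyr::pivot_wider(names_from = "col", values_from = "val")
    mat <- matrix(0, n, ncol(wide) - 1,
                  dimnames = list(NULL, names(wide)[-1]))
    mat[wide$.entry, ] <- as.matrix(wide[, -1])
    mat[is.na(mat)] <- 0
    mat
  }

  count_block <- function(rows, key_col, date_col, name_of, family, w) {
    joined <- rows |>
      dplyr::inner_join(ent, by = "person_id",
                        relationship = "many-to-many") |>
      dplyr::mutate(day = as.numeric(.data[[date_col]] - .data$index_date)) |>
      dplyr::filter(.data$day >= w[1], .data$day <= 0)
    if (nrow(joined) == 0) return(NULL)
    wide <- joined |>
      dplyr::count(.data$.entry, .data[[key_col]]) |>
      dplyr::mutate(col = paste0(family, " during day ", w[1],
                                 " through 0 days relative to index: ",
                                 name_of(.data[[key_col]]))) |>
      dplyr::select(".entry", "col", "n") |>
      tidyr::pivot_wider(names_from = "col", values_from = "n",
                         values_fill = 0)
    mat <- matrix(0, n, ncol(wide) - 1,
                  dimnames = list(NULL, names(wide)[-1]))
    mat[wide$.entry, ] <- as.matrix(wide[, -1])
    mat
  }

  meas <- cdm$measurement
  is_psg <- meas$measurement_concept_id %in% psg_concepts
  for (w in settings$windows) {
    wtag <- paste0("w", abs(w[1]))
    blocks[[paste0("psg_", wtag)]] <- value_block(
      meas[is_psg, ], "measurement_concept_id", "value_as_number",
      "measurement_date",
      function(id) unname(psg_names[as.character(id)]),
      "measurement value", w)
    if (settings$setting == "all") {
      blocks[[paste0("lab_", wtag)]] <- value_block(
        meas[!is_psg, ], "measurement_source_value", "value_as_number",
        "measurement_date", identity, "measurement value", w)
      blocks[[paste0("obs_", wtag)]] <- value_block(
        cdm$observation, "observation_source_value", "value_as_number",
        "observation_date", identity, "observation value", w)
      cond <- dplyr::mutate(cdm$condition_occurrence,
                            prefix = substr(.data$condition_source_value, 1, 3))
      blocks[[paste0("cond_", wtag)]] <- count_block(
        cond, "prefix", "condition_start_date", identity,
        "condition group", w)
      blocks[[paste0("proc_", wtag)]] <- count_block(
        cdm$procedure_occurrence, "procedure_concept_id", "procedure_date",
        as.character, "procedure", w)
      # drug eras: overlap indicator
      de <- cdm$drug_era |>
        dplyr::inner_join(ent, by = "person_id",
                          relationship = "many-to-many") |>
        dplyr::filter(.data$drug_era_start_date <= .data$index_date,
                      .data$drug_era_end_date >= .data$index_date + w[1])
      if (nrow(de)) {
        wide <- de |>
          dplyr::distinct(.data$.entry, .data$drug_source_value) |>
          dplyr::mutate(col = paste0("drug_era group during day ", w[1],
                                     " through 0 days relative to index: ",
                                     .data$drug_source_value),
                        v = 1) |>
          dplyr::select(".entry", "col", "v") |>
          tidyr::pivot_wider(names_from = "col", values_from = "v",
                             values_fill = 0)
        mat <- matrix(0, n, ncol(wide) - 1,
                      dimnames = list(NULL, names(wide)[-1]))
        mat[wide$.entry, ] <- as.matrix(wide[, -1])
        blocks[[paste0("drug_", wtag)]] <- mat
      }
      # visit concept counts
      blocks[[paste0("visit_", wtag)]] <- count_block(
        cdm$visit_occurrence, "visit_concept_id", "visit_start_date",
        function(id) paste0("visit concept count ", id), "visit", w)
    }
  }

  if (settings$setting == "all") {
    sex <- ifelse(gender == 8507, "male", "female")
    cond_ent <- cdm$condition_occurrence |>
      dplyr::inner_join(ent, by = "person_id",
                        relationship = "many-to-many") |>
      dplyr::filter(.data$condition_start_date <= .data$index_date) |>
      dplyr::select(".entry", code = "condition_source_value")
    batch_score <- function(map) {
      matches <- map_code_components(unique(cond_ent$code), map)
      s <- numeric(n)
      if (nrow(matches)) {
        agg <- cond_ent |>
          dplyr::inner_join(matches, by = "code",
                            relationship = "many-to-many") |>
          dplyr::group_by(.data$.entry, .data$group) |>
          dplyr::summarise(points = max(.data$points), .groups = "drop") |>
          dplyr::group_by(.data$.entry) |>
          dplyr::summarise(score = sum(.data$points), .groups = "drop")
        s[agg$.entry] <- agg$score
      }
      s
    }
    scores <- cbind(
      `Charlson index` = batch_score(charlson_component_map()),
      `CHA2DS2-VASc score` = batch_score(cha2ds2vasc_component_map()) +
        (ent$age >= 75) * 2 + (ent$age >= 65 & ent$age < 75) * 1 +
        (sex == "female") * 1,
      `DCSI score` = batch_score(dcsi_component_map()))
    blocks$scores <- scores
  }

  x <- do.call(cbind, blocks[!vapply(blocks, is.null, logical(1))])
  dropped <- character(0)
  if (n > 1) {  # variance is undefined on a single row
    variance <- apply(x, 2, stats::var)
    dropped <- colnames(x)[is.na(variance) | variance == 0]
    if (length(dropped)) {
      message("dropping ", length(dropped), " zero-variance covariate(s)")
      x <- x[, !(colnames(x) %in% dropped), drop = FALSE]
    }
  }
  if (ncol(x) > 1) x <- x[, order(colnames(x)), drop = FALSE]
  structure(list(x = x, entries = entries, setting = settings$setting,
                 dropped = dropped),
            class = "psg_covariates")
}
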