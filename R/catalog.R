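#' The PSG parameter catalog
#'
#' Loads the bundled catalog of the 86 polysomnography report parameters that
#' are standardized into the CDM: 85 in the Measurement domain and one
#' (Waist/hip ratio) in the Observation domain; 20 carry pre-existing
#' LOINC/SNOMED mappings and 66 require custom standard concepts. Each entry
#' records its reporting category, canonical name, unit, domain, mapping
#' status and the short source code used by the EHR report forms.
#'
#' @param path Path to a catalog CSV. Defaults to the bundled catalog.
#' @param validate Check the catalog invariants (default `TRUE`).
#' @return A tibble with one row per parameter, classed `psg_catalog`.
#' @examples
#' catalog <- psg_parameter_catalog()
#' dplyr::count(catalog, category)
#' @export
psg_parameter_catalog <- function(path = NULL, validate = TRUE) {
  path <- path %||% system.file("extdata", "psg_parameter_catalog.csv",
                                package = "sleepcdm", mustWork = TRUE)
  # leading "#" lines are file comments, but "#" also occurs inside
  # parameter names, so strip comment lines rather than using a comment char
  lines <- readLines(path)
  catalog <- readr::read_csv(I(paste(lines[!startsWith(lines, "#")],
                                     collapse = "\n")),
                             show_col_types = FALSE, progress = FALSE)
  catalog <- tibble::new_tibble(catalog, class = "psg_catalog")
  if (validate) validate_catalog(catalog)
  catalog
}

# Per-category sizes of the published parameter table; the catalog must match.
psg_category_counts <- function() {
  c("Body measurement" = 7, "Sleep summary" = 7, "Sleep stage" = 6,
    "Respiratory events" = 16, "Duration of apnea or hypopnea" = 4,
    "Sleep position" = 8, "Arousal" = 5, "Limb movement" = 2,
    "Snoring" = 5, "Oxygen statistics" = 8, "CPAP pressure" = 1,
    "Questionnaire" = 2, "Multiple sleep latency test" = 11,
    "Apnea level manometry test" = 1, "Friedman staging" = 3)
}

#' Validate a PSG parameter catalog
#'
#' Checks the structural invariants the vocabulary builder relies on: 86
#' entries with the published per-category counts, unique parameter names and
#' source codes, a 20/66 pre-existing/custom mapping split, and exactly one
#' Observation-domain entry (Waist/hip ratio). A count mismatch reports a
#' per-category diff.
#'
#' @param catalog A catalog tibble as returned by [psg_parameter_catalog()].
#' @return The catalog, invisibly, if valid; otherwise an error of class
#'   `sleepcdm_catalog_error`.
#' @export
validate_catalog <- function(catalog) {
  required <- c("category", "parameter_name", "unit", "domain",
                "mapping_status", "mapped_vocabulary", "source_code",
                "value_kind")
  missing_cols <- setdiff(required, names(catalog))
  if (length(missing_cols)) {
    abort_sleepcdm(paste0("catalog missing column(s): ",
                          paste(missing_cols, collapse = ", ")),
                   "sleepcdm_catalog_error")
  }
  if (anyDuplicated(catalog$parameter_name)) {
    dup <- unique(catalog$parameter_name[duplicated(catalog$parameter_name)])
    abort_sleepcdm(paste0("duplicate parameter name(s): ",
                          paste(dup, collapse = "; ")),
                   "sleepcdm_catalog_error")
  }
  if (anyDuplicated(catalog$source_code)) {
    abort_sleepcdm("duplicate source codes in catalog", "sleepcdm_catalog_error")
  }
  expected <- psg_category_counts()
  got <- table(catalog$category)
  diff <- purrr::map_int(names(expected), ~ {
    as.integer((if (.x %in% names(got)) got[[.x]] else 0L) - expected[[.x]])
  })
  names(diff) <- names(expected)
  if (nrow(catalog) != 86L || any(diff != 0L)) {
    bad <- diff[diff != 0L]
    detail <- if (length(bad)) {
      paste0(" per-category diff (got-expected): ",
             paste(names(bad), bad, sep = "=", collapse = ", "))
    } else ""
    abort_sleepcdm(
      paste0("catalog has ", nrow(catalog), " entries, expected 86.", detail),
      "sleepcdm_catalog_error",
      category_diff = diff
    )
  }
  n_pre <- sum(catalog$mapping_status == "pre-existing")
  if (n_pre != 20L || sum(catalog$mapping_status == "custom") != 66L) {
    abort_sleepcdm(paste0("mapping split is ", n_pre, " pre-existing / ",
                          sum(catalog$mapping_status == "custom"),
                          " custom; expected 20/66"),
                   "sleepcdm_catalog_error")
  }
  obs <- catalog$parameter_name[catalog$domain == "Observation"]
  if (!identical(obs, "Waist/hip ratio")) {
    abort_sleepcdm("exactly one Observation-domain entry (Waist/hip ratio) required",
                   "sleepcdm_catalog_error")
  }
  if (!all(catalog$domain %in% c("Measurement", "Observation"))) {
    abort_sleepcdm("domain must be Measurement or Observation",
                   "sleepcdm_catalog_error")
  }
  invisible(catalog)
}
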