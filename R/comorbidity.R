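# Additive comorbidity scores (Charlson, CHA2DS2-VASc, DCSI) computed from
# ICD-10 condition codes. The code-to-component maps are shipped as data
# (compact Quan-style prefix maps) and are fully replaceable; scores are sums
# of component points, with within-group hierarchies (e.g. severe liver
# disease supersedes mild) handled by taking the maximum points per group.

#' Component maps for the comorbidity scores
#'
#' Each map is a tibble of ICD-10 prefixes with the component (`group`) it
#' marks and the points it contributes. For Charlson, `group` implements the
#' standard hierarchies (diabetes with/without complications, liver disease,
#' cancer/metastasis) by keeping the maximum points per group. For DCSI,
#' `points` is the severity level of the complication category and the score
#' sums the per-category maxima.
#'
#' @return A tibble with columns `prefix`, `group`, `points`.
#' @export
charlson_component_map <- function() {
  tibble::tribble(
    ~prefix, ~group, ~points,
    "I21", "mi", 1, "I22", "mi", 1, "I25.2", "mi", 1,
    "I50", "chf", 1, "I11.0", "chf", 1, "I13.0", "chf", 1,
    "I70", "pvd", 1, "I71", "pvd", 1, "I73", "pvd", 1,
    "I60", "cvd", 1, "I61", "cvd", 1, "I62", "cvd", 1, "I63", "cvd", 1,
    "I64", "cvd", 1, "I65", "cvd", 1, "I66", "cvd", 1, "I67", "cvd", 1,
    "I69", "cvd", 1, "G45", "cvd", 1,
    "F00", "dementia", 1, "F01", "dementia", 1, "F03", "dementia", 1,
    "G30", "dementia", 1,
    "J40", "cpd", 1, "J41", "cpd", 1, "J42", "cpd", 1, "J43", "cpd", 1,
    "J44", "cpd", 1, "J45", "cpd", 1, "J46", "cpd", 1, "J47", "cpd", 1,
    "M05", "rheum", 1, "M06", "rheum", 1, "M32", "rheum", 1,
    "M33", "rheum", 1, "M34", "rheum", 1,
    "K25", "pud", 1, "K26", "pud", 1, "K27", "pud", 1, "K28", "pud", 1,
    "B18", "liver", 1, "K70", "liver", 1, "K73", "liver", 1,
    "K74", "liver", 1, "K76.0", "liver", 1,
    "I85.0", "liver", 3, "K72.1", "liver", 3, "K72.9", "liver", 3,
    "K76.6", "liver", 3, "K76.7", "liver", 3,
    "E10.9", "diabetes", 1, "E11.9", "diabetes", 1, "E13.9", "diabetes", 1,
    "E10.2", "diabetes", 2, "E10.3", "diabetes", 2, "E10.4", "diabetes", 2,
    "E10.5", "diabetes", 2, "E11.2", "diabetes", 2, "E11.3", "diabetes", 2,
    "E11.4", "diabetes", 2, "E11.5", "diabetes", 2,
    "G81", "plegia", 2, "G82", "plegia", 2, "G04.1", "plegia", 2,
    "N18", "renal", 2, "N19", "renal", 2, "N03", "renal", 2,
    "C00", "cancer", 2, "C18", "cancer", 2, "C34", "cancer", 2,
    "C50", "cancer", 2, "C61", "cancer", 2, "C81", "cancer", 2,
    "C91", "cancer", 2,
    "C77", "cancer", 6, "C78", "cancer", 6, "C79", "cancer", 6,
    "C80", "cancer", 6,
    "B20", "hiv", 6, "B21", "hiv", 6, "B22", "hiv", 6, "B24", "hiv", 6
  )
}

#' @rdname charlson_component_map
#' @export
cha2ds2vasc_component_map <- function() {
  tibble::tribble(
    ~prefix, ~group, ~points,
    "I50", "chf", 1, "I11.0", "chf", 1,
    "I10", "htn", 1, "I11", "htn", 1, "I12", "htn", 1, "I13", "htn", 1,
    "I15", "htn", 1,
    "E10", "diabetes", 1, "E11", "diabetes", 1, "E13", "diabetes", 1,
    "I60", "stroke_tia", 2, "I61", "stroke_tia", 2, "I63", "stroke_tia", 2,
    "I64", "stroke_tia", 2, "G45", "stroke_tia", 2,
    "I21", "vascular", 1, "I25", "vascular", 1, "I70", "vascular", 1,
    "I71", "vascular", 1, "I73", "vascular", 1
  )
}

#' @rdname charlson_component_map
#' @export
dcsi_component_map <- function() {
  tibble::tribble(
    ~prefix, ~group, ~points,
    "E11.3", "retinopathy", 1, "H36.0", "retinopathy", 1,
    "H35.81", "retinopathy", 2,
    "E11.2", "nephropathy", 1, "N08.3", "nephropathy", 1,
    "N18", "nephropathy", 2, "N19", "nephropathy", 2,
    "E11.4", "neuropathy", 1, "G63.2", "neuropathy", 1,
    "I60", "cerebrovascular", 1, "I61", "cerebrovascular", 2,
    "I63", "cerebrovascular", 2, "G45", "cerebrovascular", 1,
    "I20", "cardiovascular", 1, "I21", "cardiovascular", 2,
    "I25", "cardiovascular", 1, "I50", "cardiovascular", 2,
    "I70", "pvd", 1, "I73", "pvd", 1, "E11.5", "pvd", 2,
    "E10.1", "metabolic", 2, "E11.0", "metabolic", 2, "E11.1", "metabolic", 2
  )
}

# every (code, group, points) pair where a code starts with a map prefix
map_code_components <- function(codes, map) {
  if (!all(c("prefix", "group", "points") %in% names(map))) {
    abort_sleepcdm("component map needs columns prefix, group, points",
                   "sleepcdm_config_error")
  }
  codes <- unique(codes)
  if (length(codes) == 0) {
    return(tibble::tibble(code = character(0), group = character(0),
                          points = numeric(0)))
  }
  hit <- outer(codes, map$prefix, startsWith)
  idx <- which(hit, arr.ind = TRUE)
  tibble::tibble(code = codes[idx[, 1]], group = map$group[idx[, 2]],
                 points = map$points[idx[, 2]])
}

match_components <- function(codes, map) {
  m <- map_code_components(codes, map)
  m[, c("group", "points")]
}

#' Comorbidity scores from condition codes
#'
#' `compute_charlson()` sums the Charlson category points (maximum per
#' hierarchical group) over conditions on or before the index date.
#' `compute_cha2ds2vasc()` adds the age (65-74: 1; 75+: 2) and sex (female:
#' 1) points to the condition components. `compute_dcsi()` sums the maximum
#' severity per diabetes-complication category.
#'
#' @param conditions Tibble with `condition_source_value` and
#'   `condition_start_date` (a character vector of codes also works).
#' @param index_date Only conditions dated on or before this are counted
#'   (ignored when `conditions` is a bare character vector).
#' @param age,sex Age in years and `"male"`/`"female"`, for
#'   `compute_cha2ds2vasc()`.
#' @param map Component map; defaults to the matching
#'   [charlson_component_map()] family.
#' @return Integer score.
#' @examples
#' compute_cha2ds2vasc(tibble::tibble(
#'   condition_source_value = "I10",
#'   condition_start_date = as.Date("2014-01-01")),
#'   index_date = as.Date("2015-01-01"), age = 70, sex = "female")  # 3
#' @export
compute_charlson <- function(conditions, index_date = NULL,
                             map = charlson_component_map()) {
  codes <- condition_codes(conditions, index_date)
  hit <- match_components(codes, map)
  if (nrow(hit) == 0) return(0L)
  as.integer(sum(tapply(hit$points, hit$group, max)))
}

#' @rdname compute_charlson
#' @export
compute_cha2ds2vasc <- function(conditions, index_date = NULL, age, sex,
                                map = cha2ds2vasc_component_map()) {
  codes <- condition_codes(conditions, index_date)
  hit <- match_components(codes, map)
  pts <- if (nrow(hit)) sum(tapply(hit$points, hit$group, max)) else 0
  pts <- pts + (age >= 75) * 2 + (age >= 65 & age < 75) * 1 +
    (sex == "female") * 1
  as.integer(pts)
}

#' @rdname compute_charlson
#' @export
compute_dcsi <- function(conditions, index_date = NULL,
                         map = dcsi_component_map()) {
  codes <- condition_codes(conditions, index_date)
  hit <- match_components(codes, map)
  if (nrow(hit) == 0) return(0L)
  as.integer(sum(tapply(hit$points, hit$group, max)))
}

condition_codes <- function(conditions, index_date) {
  if (is.character(conditions)) return(conditions)
  x <- conditions
  if (!is.null(index_date)) {
    x <- dplyr::filter(x, .data$condition_start_date <= index_date)
  }
  x$condition_source_value
}
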