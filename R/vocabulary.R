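#' Allocate a custom standard concept id
#'
#' Custom concepts minted for unmappable PSG parameters live above the
#' 2-billion line reserved for local concepts, allocated sequentially so that
#' a fixed catalog ordering always yields the same ids.
#'
#' @param sequence_index Non-negative integer (vectorized); 0 is the first
#'   custom concept.
#' @return `2000000001 + sequence_index`, as a double (the ids exceed
#'   `.Machine$integer.max`).
#' @examples
#' allocate_custom_concept_id(0)   # 2000000001
#' allocate_custom_concept_id(65)  # 2000000066
#' @export
allocate_custom_concept_id <- function(sequence_index) {
  if (length(sequence_index) == 0) return(numeric(0))
  if (any(is.na(sequence_index)) || any(sequence_index < 0) ||
      any(sequence_index != trunc(sequence_index))) {
    abort_sleepcdm("sequence_index must be a non-negative integer",
                   "sleepcdm_vocab_error")
  }
  2000000001 + as.numeric(sequence_index)
}

# Base of the id range used for minted non-standard source concepts; keeps
# 'Maps to' edges addressable by concept_id without touching the custom
# standard range {2000000001, ...}.
SOURCE_CONCEPT_BASE <- 2100000000
# Stub ids for pre-existing standard concepts (licensed vocabulary content is
# represented by fixture stubs; see the catalog file).
PREEXISTING_STUB_BASE <- 3000000

concept_row <- function(concept_id, concept_name, domain_id, vocabulary_id,
                        concept_class_id, standard_concept, concept_code) {
  tibble::tibble(
    concept_id = as.numeric(concept_id),
    concept_name = concept_name,
    domain_id = domain_id,
    vocabulary_id = vocabulary_id,
    concept_class_id = concept_class_id,
    standard_concept = standard_concept,
    concept_code = concept_code,
    valid_start_date = as.Date("1970-01-01"),
    valid_end_date = as.Date("2099-12-31"),
    invalid_reason = NA_character_
  )
}

#' Stub concepts for the sleep-study procedures
#'
#' The four study-type procedure concepts (full-night PSG, split-night PSG,
#' CPAP-titration PSG, MSLT) plus the PSG panel concept used as the anchor of
#' the panel relationships. These are fixture stubs for standard procedure
#' concepts, with fixed ids so downstream tables are deterministic.
#'
#' @return A tibble of concept rows; the panel concept has
#'   `concept_class_id == "Panel"`.
#' @export
psg_procedure_concepts <- function() {
  dplyr::bind_rows(
    concept_row(4300000, "Polysomnography panel", "Procedure", "SNOMED",
                "Panel", "S", "SYNTH-PSG-PANEL"),
    concept_row(4300001, "Full-night polysomnography", "Procedure", "SNOMED",
                "Procedure", "S", "SYNTH-PSG-FULL"),
    concept_row(4300002, "Split-night polysomnography", "Procedure", "SNOMED",
                "Procedure", "S", "SYNTH-PSG-SPLIT"),
    concept_row(4300003, "CPAP titration polysomnography", "Procedure",
                "SNOMED", "Procedure", "S", "SYNTH-PSG-CPAP"),
    concept_row(4300004, "Multiple sleep latency test", "Procedure", "SNOMED",
                "Procedure", "S", "SYNTH-MSLT")
  )
}

# study type label -> procedure concept_id
study_type_concept_ids <- function() {
  c("full-night" = 4300001, "split-night" = 4300002,
    "CPAP-titration" = 4300003, "MSLT" = 4300004)
}

#' Build the PSG vocabulary bundle
#'
#' Turns the parameter catalog into OMOP vocabulary structures: one standard
#' concept per parameter (pre-existing stubs keep their LOINC/SNOMED identity;
#' the rest are minted as custom standard concepts with ids from
#' [allocate_custom_concept_id()]), a non-standard source concept per report
#' code, `Maps to`/`Mapped from` rows for every source code, bidirectional
#' `Panel contains` / `Contained in panel (LOINC)` rows anchoring every
#' parameter to the PSG panel concept, and self-referential ancestor rows for
#' every custom concept.
#'
#' @param catalog A [psg_parameter_catalog()] tibble. A zero-row catalog
#'   yields an empty bundle; any other size than 86 is rejected when
#'   `validate = TRUE`.
#' @param panel_concept One-row concept tibble for the PSG panel procedure
#'   (default [psg_procedure_concepts()]'s panel row).
#' @param validate Validate the catalog first (default `TRUE`).
#' @return A list of class `psg_vocabulary` with tibbles `concept`,
#'   `concept_relationship`, `concept_ancestor`, and the annotated `catalog`
#'   (columns `standard_concept_id`, `source_concept_id` added).
#' @examples
#' vocab <- build_psg_vocabulary(psg_parameter_catalog())
#' sum(vocab$concept$concept_id > 2e9 & vocab$concept$standard_concept == "S")
#' @export
build_psg_vocabulary <- function(catalog,
                                 panel_concept = NULL,
                                 validate = TRUE) {
  if (is.null(panel_concept)) {
    panel_concept <- dplyr::filter(psg_procedure_concepts(),
                                   .data$concept_class_id == "Panel")
  }
  if (nrow(catalog) == 0) {
    bundle <- list(
      concept = concept_row(numeric(0), character(0), character(0),
                            character(0), character(0), character(0),
                            character(0)),
      concept_relationship = tibble::tibble(
        concept_id_1 = numeric(0), concept_id_2 = numeric(0),
        relationship_id = character(0)),
      concept_ancestor = tibble::tibble(
        ancestor_concept_id = numeric(0), descendant_concept_id = numeric(0),
        min_levels_of_separation = integer(0),
        max_levels_of_separation = integer(0)),
      catalog = catalog
    )
    class(bundle) <- "psg_vocabulary"
    return(bundle)
  }
  if (validate) validate_catalog(catalog)

  is_custom <- catalog$mapping_status == "custom"
  standard_id <- numeric(nrow(catalog))
  standard_id[is_custom] <- allocate_custom_concept_id(seq_len(sum(is_custom)) - 1)
  standard_id[!is_custom] <- PREEXISTING_STUB_BASE + which(!is_custom)

  cat2 <- dplyr::mutate(
    tibble::as_tibble(catalog),
    standard_concept_id = standard_id,
    source_concept_id = SOURCE_CONCEPT_BASE + dplyr::row_number()
  )

  standard_concepts <- concept_row(
    cat2$standard_concept_id, cat2$parameter_name, cat2$domain,
    ifelse(is_custom, "PSG Custom", cat2$mapped_vocabulary),
    ifelse(is_custom, "Clinical Observation", "Lab Test"),
    "S",
    ifelse(is_custom, cat2$source_code, cat2$standard_code)
  )
  source_concepts <- concept_row(
    cat2$source_concept_id, paste0("PSG report field: ", cat2$parameter_name),
    cat2$domain, "PSG Source", "Source Value", NA_character_,
    cat2$source_code
  )

  maps_to <- tibble::tibble(
    concept_id_1 = cat2$source_concept_id,
    concept_id_2 = cat2$standard_concept_id,
    relationship_id = "Maps to"
  )
  mapped_from <- tibble::tibble(
    concept_id_1 = cat2$standard_concept_id,
    concept_id_2 = cat2$source_concept_id,
    relationship_id = "Mapped from"
  )
  panel_id <- panel_concept$concept_id[[1]]
  panel_contains <- tibble::tibble(
    concept_id_1 = panel_id,
    concept_id_2 = cat2$standard_concept_id,
    relationship_id = "Panel contains"
  )
  contained_in <- tibble::tibble(
    concept_id_1 = cat2$standard_concept_id,
    concept_id_2 = panel_id,
    relationship_id = "Contained in panel (LOINC)"
  )

  ancestors <- tibble::tibble(
    ancestor_concept_id = cat2$standard_concept_id[is_custom],
    descendant_concept_id = cat2$standard_concept_id[is_custom],
    min_levels_of_separation = 0L,
    max_levels_of_separation = 0L
  )

  bundle <- list(
    concept = dplyr::bind_rows(panel_concept,
                               dplyr::anti_join(psg_procedure_concepts(),
                                                panel_concept, by = "concept_id"),
                               standard_concepts, source_concepts),
    concept_relationship = dplyr::bind_rows(maps_to, mapped_from,
                                            panel_contains, contained_in),
    concept_ancestor = ancestors,
    catalog = cat2
  )
  class(bundle) <- "psg_vocabulary"
  bundle
}

#' Resolve a PSG source code to its standard concept
#'
#' Follows the single `Maps to` edge from a report field code to the standard
#' concept that measurement/observation rows are loaded under.
#'
#' @param source_code Character vector of report field codes.
#' @param bundle A `psg_vocabulary` from [build_psg_vocabulary()].
#' @return Numeric vector of standard concept ids.
#' @export
resolve_source_code <- function(source_code, bundle) {
  stopifnot(inherits(bundle, "psg_vocabulary"))
  idx <- match(source_code, bundle$catalog$source_code)
  if (anyNA(idx)) {
    bad <- unique(source_code[is.na(idx)])
    abort_sleepcdm(paste0("unmapped source code(s): ",
                          paste(bad, collapse = ", ")),
                   "sleepcdm_unmapped_code", codes = bad)
  }
  bundle$catalog$standard_concept_id[idx]
}

#' Validate a vocabulary bundle
#'
#' Structural checks on a built (or re-read) vocabulary: unique concept ids,
#' custom concepts at/above the 2-billion line flagged standard, exactly one
#' `Maps to` per source code, panel rows in exact inverse pairs, and a
#' level-0 self ancestor row for every custom concept.
#'
#' @param bundle A `psg_vocabulary`.
#' @return A tibble of violations (`check`, `detail`); zero rows when valid.
#' @export
validate_vocabulary <- function(bundle) {
  stopifnot(inherits(bundle, "psg_vocabulary"))
  v <- list()
  note <- function(check, detail) {
    v[[length(v) + 1]] <<- tibble::tibble(check = check, detail = detail)
  }
  con <- bundle$concept
  if (anyDuplicated(con$concept_id)) {
    note("unique_concept_id", paste0("duplicated id(s): ",
         paste(unique(con$concept_id[duplicated(con$concept_id)]), collapse = ",")))
  }
  custom <- dplyr::filter(con, .data$vocabulary_id == "PSG Custom")
  if (any(custom$concept_id < 2e9) ||
      any(is.na(custom$standard_concept)) ||
      any(custom$standard_concept != "S")) {
    note("custom_standard", "custom concept below 2e9 or not flagged 'S'")
  }
  rel <- bundle$concept_relationship
  mt <- dplyr::filter(rel, .data$relationship_id == "Maps to")
  dup_src <- mt$concept_id_1[duplicated(mt$concept_id_1)]
  if (length(dup_src)) {
    note("single_maps_to", paste0("source concept(s) with >1 'Maps to': ",
                                  paste(unique(dup_src), collapse = ",")))
  }
  pc <- dplyr::filter(rel, .data$relationship_id == "Panel contains")
  cp <- dplyr::filter(rel, .data$relationship_id == "Contained in panel (LOINC)")
  miss <- dplyr::anti_join(
    pc, cp, by = c(concept_id_1 = "concept_id_2", concept_id_2 = "concept_id_1"))
  miss2 <- dplyr::anti_join(
    cp, pc, by = c(concept_id_1 = "concept_id_2", concept_id_2 = "concept_id_1"))
  if (nrow(miss) || nrow(miss2)) {
    note("panel_symmetry", paste0(nrow(miss) + nrow(miss2),
                                  " panel row(s) without inverse"))
  }
  anc <- bundle$concept_ancestor
  self_ok <- custom$concept_id %in%
    anc$ancestor_concept_id[anc$ancestor_concept_id == anc$descendant_concept_id &
                              anc$min_levels_of_separation == 0L]
  if (!all(self_ok)) {
    note("self_ancestor", paste0(sum(!self_ok),
                                 " custom concept(s) without level-0 self row"))
  }
  if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(check = character(0), detail = character(0))
}

#' Write / read a vocabulary bundle as OMOP delimited files
#'
#' Emits `CONCEPT.csv`, `CONCEPT_RELATIONSHIP.csv` and `CONCEPT_ANCESTOR.csv`
#' with v5.3.1 column names (dates ISO-8601), plus the annotated catalog as
#' `PSG_CATALOG.csv` so the bundle round-trips.
#'
#' @param bundle A `psg_vocabulary`.
#' @param dir Output directory (created if absent).
#' @return `write_vocabulary()` the directory, invisibly; `read_vocabulary()`
#'   a `psg_vocabulary`.
#' @export
write_vocabulary <- function(bundle, dir) {
  stopifnot(inherits(bundle, "psg_vocabulary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(bundle$concept, file.path(dir, "CONCEPT.csv"), na = "")
  readr::write_csv(bundle$concept_relationship,
                   file.path(dir, "CONCEPT_RELATIONSHIP.csv"), na = "")
  readr::write_csv(bundle$concept_ancestor,
                   file.path(dir, "CONCEPT_ANCESTOR.csv"), na = "")
  readr::write_csv(bundle$catalog, file.path(dir, "PSG_CATALOG.csv"), na = "")
  invisible(dir)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(dir) {
  read1 <- function(f) readr::read_csv(file.path(dir, f),
                                       show_col_types = FALSE, progress = FALSE)
  bundle <- list(
    concept = read1("CONCEPT.csv"),
    concept_relationship = read1("CONCEPT_RELATIONSHIP.csv"),
    concept_ancestor = read1("CONCEPT_ANCESTOR.csv"),
    catalog = tibble::new_tibble(read1("PSG_CATALOG.csv"), class = "psg_catalog")
  )
  class(bundle) <- "psg_vocabulary"
  bundle
}
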