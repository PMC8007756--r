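# Seeded synthetic sleep-center EHR. The generator's defaults are the study
# conditions reported for the source cohort wherever those were printed
# (study-type mix, gender mix, age-band and study-year weights, AHI severity
# mixture); everything else (per-parameter distributions, comorbidity
# prevalences, the planted outcome model) is a documented plausible choice,
# since the record-level source data are restricted.

#' Generator configuration
#'
#' @param n_persons Number of synthetic persons.
#' @param seed Mandatory integer seed; same seed, same output.
#' @param study_type_mix Named proportions over the four study types
#'   (defaults: the reported 7191/2725/1474/407 split of 11,797 studies).
#' @param male_fraction Fraction of tests on male patients (default
#'   8363/11392).
#' @param age_band_weights Weights for 10-year age bands 0-9 .. 90-99
#'   (default: the reported per-band record counts).
#' @param year_weights Named weights over study years 2004-2019 (default:
#'   the reported yearly counts).
#' @param severity_weights Target AHI-severity mixture
#'   normal/mild/moderate/severe (default: the reported 3209/2681/2167/3193
#'   counts over 11,250 AHI-bearing tests; note the source text rounds the
#'   severe share to 28.4%).
#' @param ahi_missing Probability an otherwise AHI-bearing study lacks an
#'   AHI value (default 0.0125, matching 142/11,392).
#' @param param_missing Per-parameter missingness for the remaining report
#'   fields (default 0.10).
#' @param second_test_prob Probability of a second sleep test per person
#'   (default 0.19, giving about 1.2 tests per person).
#' @param form_version_weights Weights over form versions 1-11 (default
#'   uniform).
#' @param outcome_coefs Logistic coefficients of the planted
#'   cardio-neuro-metabolic outcome model on age, AHI, lowest SpO2 and
#'   comorbidity count; see Details.
#' @param prior_outcome_prob Probability of a planted pre-index outcome
#'   condition (exercises the prior-outcome exclusion; default 0.05).
#'
#' @details The planted outcome model is
#'   `logit(p) = b0 + b_age (age-50) + b_ahi (ahi-20) + b_spo2 (85-lowSpO2) +
#'   b_com k`, where `k` counts background comorbidities, and `p` is the
#'   probability of an outcome within 1095 days of the test; event times are
#'   exponential with the rate matched to `p`.
#' @return A validated list of class `sleep_generator_config`.
#' @export
generator_config <- function(n_persons,
                             seed,
                             study_type_mix = c("full-night" = 7191,
                                                "split-night" = 2725,
                                                "CPAP-titration" = 1474,
                                                "MSLT" = 407) / 11797,
                             male_fraction = 8363 / 11392,
                             age_band_weights = c(205, 385, 565, 1229, 2230,
                                                  2849, 2348, 1226, 346, 9),
                             year_weights = stats::setNames(
                               c(319, 458, 546, 702, 639, 605, 604, 647, 677,
                                 685, 860, 1014, 1067, 1023, 1035, 511),
                               2004:2019),
                             severity_weights = c(normal = 3209, mild = 2681,
                                                  moderate = 2167,
                                                  severe = 3193) / 11250,
                             ahi_missing = 0.0125,
                             param_missing = 0.10,
                             second_test_prob = 0.19,
                             form_version_weights = rep(1, 11),
                             outcome_coefs = c(intercept = -2.7, age = 0.04,
                                               ahi = 0.025, spo2 = 0.04,
                                               comorbidity = 1.0),
                             prior_outcome_prob = 0.05) {
  if (missing(seed) || is.null(seed)) {
    abort_sleepcdm("seed is mandatory", "sleepcdm_config_error")
  }
  check_prop <- function(p, what) {
    if (any(p < 0) || abs(sum(p / sum(p)) - 1) > 1e-9) {
      abort_sleepcdm(paste0("invalid proportions for ", what),
                     "sleepcdm_config_error")
    }
  }
  if (abs(sum(study_type_mix) - 1) > 1e-9 || any(study_type_mix < 0)) {
    abort_sleepcdm("study_type_mix must be proportions summing to 1",
                   "sleepcdm_config_error")
  }
  if (abs(sum(severity_weights) - 1) > 1e-9 || any(severity_weights < 0)) {
    abort_sleepcdm("severity_weights must be proportions summing to 1",
                   "sleepcdm_config_error")
  }
  check_prop(age_band_weights, "age_band_weights")
  check_prop(year_weights, "year_weights")
  check_prop(form_version_weights, "form_version_weights")
  structure(list(
    n_persons = as.integer(n_persons), seed = as.integer(seed),
    study_type_mix = study_type_mix, male_fraction = male_fraction,
    age_band_weights = age_band_weights / sum(age_band_weights),
    year_weights = year_weights / sum(year_weights),
    severity_weights = severity_weights,
    ahi_missing = ahi_missing, param_missing = param_missing,
    second_test_prob = second_test_prob,
    form_version_weights = form_version_weights / sum(form_version_weights),
    outcome_coefs = outcome_coefs,
    prior_outcome_prob = prior_outcome_prob
  ), class = "sleep_generator_config")
}

#' Classify OSA severity from the apnea-hypopnea index
#'
#' Severity bands as used throughout sleep medicine: normal below 5 events/h,
#' mild in \[5, 15), moderate in \[15, 30), severe at 30 and above.
#'
#' @param ahi Numeric vector of AHI values (events per hour of sleep);
#'   `NA` passes through.
#' @return Factor with levels normal/mild/moderate/severe.
#' @examples
#' classify_osa_severity(c(4.9, 5, 17.3, 30))
#' @export
classify_osa_severity <- function(ahi) {
  if (any(!is.na(ahi) & ahi < 0)) {
    abort_sleepcdm("ahi must be non-negative", "sleepcdm_domain_error")
  }
  cut(ahi, breaks = c(-Inf, 5, 15, 30, Inf), right = FALSE,
      labels = c("normal", "mild", "moderate", "severe"))
}

# Draw an AHI from the severity mixture; within-band shapes are smooth betas
# (severe: shifted gamma), a plausible non-reported choice.
draw_ahi <- function(n, weights) {
  cls <- sample(names(weights), n, replace = TRUE, prob = weights)
  val <- numeric(n)
  idx <- cls == "normal";   val[idx] <- 5 * stats::rbeta(sum(idx), 1.2, 1.6)
  idx <- cls == "mild";     val[idx] <- 5 + 10 * stats::rbeta(sum(idx), 1.2, 1.2)
  idx <- cls == "moderate"; val[idx] <- 15 + 15 * stats::rbeta(sum(idx), 1.2, 1.2)
  idx <- cls == "severe";   val[idx] <- pmin(30 + stats::rgamma(sum(idx), 1.3,
                                                                scale = 14), 150)
  round(val, 1)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# which catalog categories a study type reports
categories_for_study_type <- function(study_type) {
  base <- c("Body measurement", "Sleep summary", "Sleep stage",
            "Respiratory events", "Duration of apnea or hypopnea",
            "Sleep position", "Arousal", "Limb movement", "Snoring",
            "Oxygen statistics", "Questionnaire",
            "Apnea level manometry test", "Friedman staging")
  switch(study_type,
         "full-night" = base,
         "split-night" = base,
         "CPAP-titration" = c(base, "CPAP pressure"),
         "MSLT" = c("Body measurement", "Multiple sleep latency test",
                    "Questionnaire"))
}

# Generate canonical parameter values for one test. ahi/low_spo2 are supplied
# so respiratory and oxygen families cohere; returns a named numeric vector.
draw_parameters <- function(catalog, study_type, ahi, low_spo2) {
  cats <- categories_for_study_type(study_type)
  sub <- catalog[catalog$category %in% cats, ]
  ht <- round(stats::rnorm(1, 168, 9), 1)
  wt <- round(stats::rnorm(1, 75, 14), 1)
  waist <- round(stats::rnorm(1, 92, 12), 1)
  hip <- round(stats::rnorm(1, 99, 9), 1)
  tib <- round(stats::rnorm(1, 450, 35), 1)
  se <- round(100 * stats::rbeta(1, 8, 2), 1)
  tst <- round(tib * se / 100, 1)
  vals <- vapply(seq_len(nrow(sub)), function(i) {
    code <- sub$source_code[i]
    kind <- sub$value_kind[i]
    switch(code,
      HT = ht, WT = wt, BMI = round(wt / (ht / 100)^2, 1),
      NECK_C = round(stats::rnorm(1, 38, 4), 1),
      WAIST_C = waist, HIP_C = hip, WHR = round(waist / hip, 2),
      TIB_MIN = tib, SE_PCT = se, TST_MIN = tst,
      SPT_MIN = round(tib * stats::runif(1, 0.9, 1), 1),
      WASO_MIN = round(max(tib - tst - stats::runif(1, 0, 20), 0), 1),
      AHI_TOTAL = ahi,
      LOW_SPO2 = low_spo2,
      AVG_SPO2 = round(clamp(low_spo2 + stats::runif(1, 2, 8), 50, 99), 1),
      WAKE_SPO2 = round(clamp(low_spo2 + stats::runif(1, 3, 10), 50, 99), 1),
      ODI = round(clamp(ahi * stats::runif(1, 0.6, 1.1), 0, 150), 1),
      {
        if (grepl("^AHI_|^OAI$|^CAI$|^MAI$|^AI$|^HI", code)) {
          round(ahi * stats::rbeta(1, 2, 4), 1)
        } else if (code %in% c("RDI", "RERA")) {
          round(ahi * stats::runif(1, 0.9, 1.3) + stats::rexp(1, 1), 1)
        } else {
          switch(kind,
            percentage = round(100 * stats::rbeta(1, 2, 3), 1),
            duration_min = round(stats::rgamma(1, 3, scale = 15), 1),
            duration_sec = round(stats::rgamma(1, 4, scale = 8), 1),
            index = round(stats::rexp(1, 1 / 8), 1),
            count = stats::rpois(1, 25),
            score = round(24 * stats::rbeta(1, 2, 3)),
            grade = sample(1:4, 1),
            pressure = round(stats::runif(1, 4, 16), 1),
            round(stats::rexp(1, 1 / 10), 1))
        }
      })
  }, numeric(1))
  stats::setNames(vals, sub$source_code)
}

# ICD-10 prefixes of the default cardio-neuro-metabolic outcome set.
#' Default cardio-neuro-metabolic outcome code list
#'
#' ICD-10 prefixes defining the outcome phenotype (hypertensive, ischaemic
#' heart, atrial fibrillation, cerebrovascular and diabetes codes). The
#' published study's exact list is in an unavailable supplement; this default
#' is a replaceable configuration.
#'
#' @return Character vector of ICD-10 prefixes.
#' @export
default_outcome_codes <- function() {
  c(paste0("I1", 0:5), paste0("I2", 0:5), "I48", paste0("I6", 0:9),
    paste0("E0", 8:9), paste0("E1", 0:4))
}

run_seeded <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic sleep-center EHR
#'
#' Produces everything downstream modules need: versioned source PSG reports
#' (field names and units in the dialect of their form version), a
#' pre-existing CDM bundle (persons, observation periods, visits, PSG
#' procedure orders, background conditions, drug eras, a few routine
#' laboratory measurements), and ground-truth outcome labels from the planted
#' risk model. Reproducible: the same config yields byte-identical output.
#'
#' @param config A [generator_config()].
#' @param catalog A [psg_parameter_catalog()] tibble.
#' @return A list of class `sleep_ehr` with elements `reports` (tibble with
#'   list-column `fields`), `cdm` (a `cdm_bundle`), and `truth` (per-test
#'   tibble: AHI, lowest SpO2, comorbidity count, outcome probability, event
#'   indicator and day).
#' @export
generate_sleep_ehr <- function(config, catalog = psg_parameter_catalog()) {
  stopifnot(inherits(config, "sleep_generator_config"))
  run_seeded(config$seed, generate_sleep_ehr_impl(config, catalog))
}

generate_sleep_ehr_impl <- function(config, catalog) {
  n <- config$n_persons
  if (n == 0) {
    return(structure(list(
      reports = tibble::tibble(report_id = character(0),
                               source_person_id = character(0),
                               study_date = as.Date(character(0)),
                               study_type = character(0),
                               form_version = integer(0),
                               order_reference = character(0),
                               fields = list()),
      cdm = cdm_bundle(),
      truth = tibble::tibble(report_id = character(0), person_id = numeric(0),
                             ahi = numeric(0), low_spo2 = numeric(0),
                             comorbidity_count = integer(0),
                             p_outcome = numeric(0), event = integer(0),
                             event_day = numeric(0))
    ), class = "sleep_ehr"))
  }
  vmap <- default_form_version_maps(catalog)

  male <- stats::rbinom(n, 1, config$male_fraction)
  band <- sample(seq_along(config$age_band_weights), n, replace = TRUE,
                 prob = config$age_band_weights)
  age1 <- (band - 1) * 10 + sample(0:9, n, replace = TRUE)

  n_tests <- 1L + stats::rbinom(n, 1, config$second_test_prob)
  person_of_test <- rep(seq_len(n), n_tests)
  first_of_test <- !duplicated(person_of_test)
  nt <- length(person_of_test)

  year1 <- as.integer(sample(names(config$year_weights), n, replace = TRUE,
                             prob = config$year_weights))
  date1 <- as.Date(paste0(year1, "-01-01")) + sample(0:364, n, replace = TRUE)
  study_date <- as.Date(rep(NA, nt), origin = "1970-01-01")
  study_date[first_of_test] <- date1
  study_date[!first_of_test] <- date1[person_of_test[!first_of_test]] +
    sample(100:700, sum(!first_of_test), replace = TRUE)

  study_type <- sample(names(config$study_type_mix), nt, replace = TRUE,
                       prob = config$study_type_mix)
  form_version <- sample(1:11, nt, replace = TRUE,
                         prob = config$form_version_weights)

  ahi <- draw_ahi(nt, config$severity_weights)
  low_spo2 <- round(clamp(97 - 0.35 * ahi + stats::rnorm(nt, 0, 4), 40, 99), 1)

  # background comorbidities (outside the outcome code list) and their drugs
  com_lipid <- stats::rbinom(n, 1, 0.20)
  com_copd <- stats::rbinom(n, 1, 0.15)
  com_gerd <- stats::rbinom(n, 1, 0.15)
  com_count <- com_lipid + com_copd + com_gerd

  age_at_test <- age1[person_of_test] +
    as.integer((study_date - date1[person_of_test]) / 365.25)
  b <- config$outcome_coefs
  lp <- b[["intercept"]] + b[["age"]] * (age_at_test - 50) +
    b[["ahi"]] * (ahi - 20) + b[["spo2"]] * (85 - low_spo2) +
    b[["comorbidity"]] * com_count[person_of_test]
  p_outcome <- stats::plogis(lp)
  rate <- -log(1 - p_outcome) / 1095
  t_event <- stats::rexp(nt, rate)
  event <- as.integer(t_event <= 1095)
  event_day <- ifelse(event == 1, ceiling(t_event), NA_real_)

  # observation periods: mostly generous lookback and follow-up, with
  # deliberate short tails so the cohort attrition steps have work to do
  lb_class <- sample(1:4, n, replace = TRUE, prob = c(.70, .15, .10, .05))
  lookback <- c(sample(365:3000, n, TRUE), sample(180:364, n, TRUE),
                sample(30:179, n, TRUE), sample(5:29, n, TRUE))[
                  (lb_class - 1) * n + seq_len(n)]
  fu_class <- sample(1:2, n, replace = TRUE, prob = c(.80, .20))
  followup <- ifelse(fu_class == 1, sample(1100:2500, n, TRUE),
                     sample(200:1093, n, TRUE))

  report_id <- sprintf("RPT%06d", seq_len(nt))

  reports_fields <- vector("list", nt)
  for (i in seq_len(nt)) {
    vals <- draw_parameters(catalog, study_type[i], ahi[i], low_spo2[i])
    drop <- stats::runif(length(vals)) < config$param_missing
    drop[names(vals) == "AHI_TOTAL"] <-
      stats::runif(sum(names(vals) == "AHI_TOTAL")) < config$ahi_missing
    vals <- vals[!drop]
    vm <- vmap[vmap$form_version == form_version[i], ]
    idx <- match(names(vals), vm$source_code)
    reports_fields[[i]] <- as.list(stats::setNames(vals / vm$factor[idx],
                                                   vm$source_field[idx]))
  }

  person <- tibble::tibble(
    person_id = as.numeric(seq_len(n)),
    gender_concept_id = ifelse(male == 1, 8507, 8532),
    year_of_birth = year1 - age1,
    person_source_value = sprintf("SRC%06d", seq_len(n))
  )
  first_date <- date1
  last_date <- stats::aggregate(study_date, list(person_of_test), max)$x
  observation_period <- tibble::tibble(
    observation_period_id = as.numeric(seq_len(n)),
    person_id = as.numeric(seq_len(n)),
    observation_period_start_date = first_date - lookback,
    observation_period_end_date = last_date + followup
  )
  visit_occurrence <- tibble::tibble(
    visit_occurrence_id = as.numeric(seq_len(nt)),
    person_id = as.numeric(person_of_test),
    visit_concept_id = 9201,  # inpatient overnight stay
    visit_start_date = study_date,
    visit_end_date = study_date + 1
  )
  # a small fraction of orders dated the day before the overnight study
  order_offset <- ifelse(stats::runif(nt) < 0.10, -1L, 0L)
  procedure_occurrence <- tibble::tibble(
    procedure_occurrence_id = as.numeric(seq_len(nt)),
    person_id = as.numeric(person_of_test),
    procedure_concept_id = unname(study_type_concept_ids()[study_type]),
    procedure_date = study_date + order_offset,
    visit_occurrence_id = as.numeric(seq_len(nt))
  )

  cond_rows <- list()
  add_cond <- function(pid, code, date) {
    cond_rows[[length(cond_rows) + 1]] <<- tibble::tibble(
      person_id = as.numeric(pid), condition_source_value = code,
      condition_start_date = date)
  }
  pre_day <- function(pid) first_date[pid] - sample(10:300, length(pid), TRUE)
  # chronic comorbidities recur: an early occurrence plus a recent one inside
  # the covariate lookback, as chronic diagnoses do in a visit-based EHR
  for (com in list(list(com_lipid, "E78.5"), list(com_copd, "J44.9"),
                   list(com_gerd, "K21.0"))) {
    pid <- which(com[[1]] == 1)
    if (length(pid)) {
      add_cond(pid, com[[2]], pre_day(pid))
      add_cond(pid, com[[2]],
               first_date[pid] - sample(1:150, length(pid), TRUE))
    }
  }
  noise_pid <- which(stats::rbinom(n, 1, 0.25) == 1)
  if (length(noise_pid)) add_cond(noise_pid, "J30.1", pre_day(noise_pid))
  # planted prior outcomes (pre-index occurrences of outcome codes)
  prior_pid <- which(stats::runif(n) < config$prior_outcome_prob)
  if (length(prior_pid)) {
    add_cond(prior_pid,
             sample(c("I10", "E11.9", "I63.9"), length(prior_pid), TRUE),
             pre_day(prior_pid))
  }
  # outcome events in continuous time after the (first) qualifying test
  ev <- which(event == 1)
  if (length(ev)) {
    add_cond(person_of_test[ev],
             sample(c("I10", "I20.9", "I48.0", "I63.9", "E11.9"),
                    length(ev), TRUE),
             study_date[ev] + event_day[ev])
  }
  condition_occurrence <- dplyr::bind_rows(cond_rows)
  if (nrow(condition_occurrence)) {
    condition_occurrence <- condition_occurrence |>
      dplyr::mutate(
        condition_occurrence_id = as.numeric(dplyr::row_number()),
        condition_concept_id = 0,
        condition_end_date = .data$condition_start_date
      ) |>
      dplyr::select(dplyr::all_of(cdm_table_spec()$condition_occurrence))
  } else condition_occurrence <- empty_cdm_table("condition_occurrence")

  drug_rows <- list()
  add_drug <- function(pid, atc, chronic = TRUE) {
    if (!length(pid)) return()
    start <- first_date[pid] - sample(30:400, length(pid), TRUE)
    # chronic therapy persists through the index date
    end <- if (chronic) first_date[pid] + sample(100:600, length(pid), TRUE)
    else start + sample(30:180, length(pid), TRUE)
    drug_rows[[length(drug_rows) + 1]] <<- tibble::tibble(
      person_id = as.numeric(pid), drug_source_value = atc,
      drug_era_start_date = start, drug_era_end_date = end)
  }
  add_drug(which(com_lipid == 1 & stats::runif(n) < 0.8), "C10AA")
  add_drug(which(com_copd == 1 & stats::runif(n) < 0.7), "R03AC")
  add_drug(which(com_gerd == 1 & stats::runif(n) < 0.7), "A02BC")
  add_drug(which(stats::runif(n) < 0.04), "A03AC", chronic = FALSE)
  drug_era <- dplyr::bind_rows(drug_rows)
  if (nrow(drug_era)) {
    atc_ids <- c(C10AA = 21601855, R03AC = 21603248, A02BC = 21600095,
                 A03AC = 21600396)  # ATC-group stub concept ids
    drug_era <- drug_era |>
      dplyr::mutate(drug_era_id = as.numeric(dplyr::row_number()),
                    drug_concept_id = unname(atc_ids[.data$drug_source_value])) |>
      dplyr::select(dplyr::all_of(cdm_table_spec()$drug_era))
  } else drug_era <- empty_cdm_table("drug_era")

  # routine pre-index laboratory measurements, correlated with the
  # comorbidity burden so the non-PSG covariate families carry real signal
  lab_specs <- list(
    list(code = "LAB_TG", concept = 3050001, base = 110, slope = 35, sd = 30),
    list(code = "LAB_SBP", concept = 3050002, base = 118, slope = 6, sd = 12),
    list(code = "LAB_GGT", concept = 3050003, base = 30, slope = 12, sd = 15))
  lab_rows <- purrr::map(lab_specs, function(ls) {
    pid <- which(stats::runif(n) < 0.7)
    if (!length(pid)) return(NULL)
    tibble::tibble(
      person_id = as.numeric(pid),
      measurement_concept_id = ls$concept,
      measurement_date = first_date[pid] - sample(1:170, length(pid), TRUE),
      value_as_number = round(pmax(ls$base + ls$slope * com_count[pid] +
                                     stats::rnorm(length(pid), 0, ls$sd), 1), 1),
      measurement_source_value = ls$code)
  })
  measurement <- dplyr::bind_rows(lab_rows)
  if (nrow(measurement)) {
    measurement <- measurement |>
      dplyr::mutate(measurement_id = as.numeric(dplyr::row_number()),
                    unit_concept_id = 0, visit_occurrence_id = NA_real_,
                    modifier_of_event_id = NA_real_,
                    modifier_of_field_concept_id = NA_real_) |>
      dplyr::select(dplyr::all_of(cdm_table_spec()$measurement))
  } else measurement <- empty_cdm_table("measurement")

  reports <- tibble::tibble(
    report_id = report_id,
    source_person_id = person$person_source_value[person_of_test],
    study_date = study_date,
    study_type = study_type,
    form_version = form_version,
    order_reference = sprintf("ORD%06d", seq_len(nt)),
    fields = reports_fields
  )
  cdm <- cdm_bundle(
    person = person, observation_period = observation_period,
    visit_occurrence = visit_occurrence,
    procedure_occurrence = procedure_occurrence,
    measurement = measurement,
    condition_occurrence = condition_occurrence, drug_era = drug_era)
  truth <- tibble::tibble(
    report_id = report_id, person_id = as.numeric(person_of_test),
    study_type = study_type, age_at_test = age_at_test,
    ahi = ahi, low_spo2 = low_spo2,
    comorbidity_count = com_count[person_of_test],
    p_outcome = p_outcome, event = event, event_day = event_day)
  structure(list(reports = reports, cdm = cdm, truth = truth),
            class = "sleep_ehr")
}

#' Write synthetic source reports as a delimited file
#'
#' Long format: one row per populated field
#' (`report_id, source_person_id, study_date, study_type, form_version,
#' order_reference, field, raw_value`). [read_source_reports()] restores the
#' nested tibble.
#'
#' @param reports Report tibble from [generate_sleep_ehr()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_source_reports <- function(reports, path) {
  long <- reports |>
    dplyr::mutate(field = purrr::map(.data$fields, names),
                  raw_value = purrr::map(.data$fields, ~ unlist(.x, use.names = FALSE))) |>
    dplyr::select(-"fields") |>
    tidyr::unnest(c("field", "raw_value"))
  readr::write_csv(long, path, na = "")
  invisible(path)
}

#' @rdname write_source_reports
#' @export
read_source_reports <- function(path) {
  long <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  long |>
    dplyr::group_by(.data$report_id, .data$source_person_id, .data$study_date,
                    .data$study_type, .data$form_version,
                    .data$order_reference) |>
    dplyr::summarise(fields = list(as.list(stats::setNames(.data$raw_value,
                                                           .data$field))),
                     .groups = "drop") |>
    dplyr::arrange(.data$report_id)
}
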