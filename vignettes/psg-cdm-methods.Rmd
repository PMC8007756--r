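---
title: "Methods: converting polysomnography reports to the OMOP CDM and testing their predictive use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: converting polysomnography reports to the OMOP CDM and testing their predictive use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepcdm)
```

`sleepcdm` standardizes structured polysomnography (PSG) report data into
the OMOP Common Data Model v5.3.1 and provides a feasibility harness for
patient-level prediction on the converted data. This vignette documents the
model behind each stage, the tunable parameters and their defaults, the
numerical conventions, and what the synthetic test bed does and does not
demonstrate.

## The parameter catalog and the custom vocabulary

The unit of conversion is a catalog of 86 PSG report parameters grouped into
fifteen reporting categories (body measurement, sleep summary, sleep stage,
respiratory events, apnea/hypopnea durations, sleep position, arousals, limb
movement, snoring, oxygen statistics, CPAP pressure, questionnaires, MSLT,
apnea-level manometry, Friedman staging). All parameters are numeric
measurements except the waist/hip ratio, which is an *observation*; ordinal
clinical grades (tonsil grade, Mallampati grade, Friedman stage) are stored
as `value_as_number` with their standard integer scales (1–4, 1–4, 1–3),
because the measurement table has no ordinal type and the grades are
universally reported as integers.

One catalog subtlety: the published sleep-stage category enumerates five
parameter names while the category totals require six; the bundled catalog
adds "% stage 3 NREM time (min)" as the sixth entry (flagged in the catalog
file) so the categories sum to 86. The split of 20 pre-existing
LOINC/SNOMED mappings versus 66 custom concepts is likewise pinned by the
totals, but the identity of the 20 is not public. The catalog assigns
pre-existing status to the seven body measurements plus thirteen widely
coded sleep measures (sleep efficiency, sleep latency, total sleep time, REM
latency, AHI, apnea index, hypopnea index, ODI, lowest and average SpO₂,
Epworth scale, Pittsburgh index, mean sleep latency) — a deterministic
choice that reproduces the 20/66 split. Where a real LOINC code is publicly
well known (height 8302-2, weight 29463-7, BMI 39156-5, waist 8280-0, AHI
90561-2, TST 93832-4) it is used; the rest are synthetic stubs marked
`SYNTH-` because licensed vocabulary content cannot be redistributed.

Custom standard concepts are allocated `2000000001 + k` in catalog row order
(`allocate_custom_concept_id()`), giving a gapless, reproducible id range
above the 2-billion line reserved for local concepts; they carry
`standard_concept = "S"` and vocabulary id `PSG Custom`. Source report codes
are minted as *non-standard* concepts in a separate range (2.1·10⁹) so that
`Maps to` edges are ordinary concept-to-concept rows; every source code has
exactly one `Maps to` target and the inverse `Mapped from`. The whole panel
is anchored to a PSG panel procedure concept through bidirectional
`Panel contains` / `Contained in panel (LOINC)` rows (2 × 86 = 172), and
every custom concept is its own ancestor and descendant at separation 0.
`validate_vocabulary()` re-checks all of these invariants on any bundle,
including one re-read from disk.

## ETL: versioned extraction, linkage, idempotent load

Source reports arrive in the dialect of one of 11 historical form revisions.
The real dialects are unpublished, so the package ships synthetic stand-ins
(`default_form_version_maps()`): versions differ in field-naming scheme and
two unit quirks (height in metres in versions 1–2; sleep efficiency as a 0–1
fraction in versions 1–3). The maps are plain data — a site would replace
them with its own. Extraction emits only fields that are present and
mappable; missing fields are omitted, never zero-filled, and unmappable
fields are skipped with a warning and counted.

Each report is linked to an *existing* PSG procedure order for the same
person and study type, choosing the nearest `procedure_date` within ±1 day
(configurable; overnight studies are often ordered the previous day), with
ties broken to the earliest date and then the lowest id so that re-runs are
byte-identical. Reports with no candidate order are quarantined with a
reason, never silently dropped, and stay out of the load ledger so they can
be retried. Loaded measurement rows point back at their procedure through
`modifier_of_event_id` with `modifier_of_field_concept_id = 1147082` (the
field concept denoting `procedure_occurrence.procedure_occurrence_id` under
the oncology-extension linkage convention; the filler value is a documented
constant because only the fields, not the filler, are standardized).
Observation rows use `observation_event_id` / `obs_event_field_concept_id`
the same way. The load is idempotent under a report-id ledger: re-running
the same batch adds nothing. Split-night studies are loaded under their own
procedure concept; their values are interpreted as the diagnostic portion of
the night.

Conservation holds by construction and is asserted in the tests: rows
loaded = populated mappable fields − fields of quarantined reports.

## Data-quality rules

The original cleaning rules are not public, so `default_rule_set()` declares
stand-ins derived from each parameter's value kind: percentages in [0, 100],
SpO₂ in (0, 100], BMI in (10, 100), all indices, durations, counts, scores,
grades and anthropometrics non-negative, and the cross-field constraint that
total sleep time cannot exceed time in bed (the TST row is removed when it
does, being the derived quantity). Rules are data (a tibble / CSV), applied
in order with first-matching-rule attribution, so the per-rule ledger sums
exactly to the removed rows; the kept set is a fixed point (re-application
removes nothing), and adding a rule can only shrink it.

## Cohorts, time-at-risk, and prediction

The feasibility cohort is adult (≥ 18 at the test) full-night PSG tests with
at least 30/90/180 days of pre-index observation (90 by default), a full
time-at-risk — observation extending at least `index + 1094` days — and no
outcome on or before index. Time-at-risk is days 1–1095 after the test,
inclusive at both ends; "1094 days" is operationalized as
`observation_period_end ≥ index + 1094`. One entry per person is kept (the
earliest qualifying test) to avoid within-person label leakage; a flag
restores all tests. Every filter appends a row to the attrition ledger,
which is monotone non-increasing by construction. The outcome is any
occurrence of a cardio-neuro-metabolic ICD-10 code (default prefixes
I10–I15, I20–I25, I48, I60–I69, E08–E14 — a replaceable configuration, since
the published list is in an unavailable supplement) dated inside
time-at-risk.

Covariates are built over windows ending at day 0 ([−7, 0], [−30, 0],
[−180, 0]): most recent in-window value for measurement/observation
covariates, in-window totals for condition groups (3-character ICD-10
prefix), procedures and visits, overlap indicators for drug eras, and the
Charlson, CHA₂DS₂-VASc and DCSI scores computed from all conditions on or
before index. The score code-to-component maps are compact Quan-style ICD-10
prefix tables shipped as data; scores are sums of per-group maxima, which
implements the standard hierarchies (complicated diabetes supersedes
uncomplicated, severe liver disease supersedes mild, metastasis supersedes
localized cancer). The `psg_only` setting keeps only gender, 5-year age
group and the PSG parameters (age is binned at 5 years for covariates and 10
years for demographic reporting). Nothing after day 0 is read — the test
suite verifies that scrambling all post-index data leaves the covariate
matrix bit-identical. Zero-variance columns are dropped with a log line.

Models follow the feasibility design: 25% training / 75% testing (kept as
designed although unconventional; configurable), hyper-parameters by 5-fold
CV on the training set only. The grids are deliberately small because the
design specifies CV but not grids: the full regularization path for the
lasso (`cv.glmnet`), mtry ∈ {√p, p/3} at 500 trees for the random forest
(ranger, impurity importance), depth ∈ {2, 3} × learning rate ∈ {0.1, 0.3}
at 60 rounds for gradient boosting (xgboost, gain importance). Test-set
discrimination is reported as AUC with a DeLong 95% CI (the CI method is
recorded in the result object) and AUPRC as step-wise average precision,
computed in-package since no installed dependency provides it. Importance
definitions differ per model (absolute lasso coefficient; impurity; gain)
and are recorded in the result metadata; rankings break ties
alphabetically. Single-class train or test partitions raise an explicit
degenerate-split error. All fits are deterministic given the seed
(single-threaded tree learners, seeded folds).

## The synthetic sleep-center EHR

`generate_sleep_ehr()` emulates the study conditions that are public as
printed margins, and fills everything else with documented plausible
choices:

* **Pinned by printed numbers** — study-type mix (7191/2725/1474/407 over
  11,797 studies), male fraction (8363/11392), 10-year age-band and
  study-year weights, and the AHI severity mixture
  (3209/2681/2167/3193 over 11,250). The severe share is printed once as
  28.5% and once as 28.4% (3193/11250 = 28.38%); the generator targets the
  counts and the summarizer reports the computed 28.4 — the discrepancy is
  documented, not resolved. About 1.25% of studies lack an AHI (142/11392),
  and a 0.19 second-test probability yields the printed 1.2 tests/person.
* **Plausible, not pinned** — within-band AHI shapes (smooth betas; severe
  is a shifted gamma capped at 150/h), per-parameter distributions by family
  (log-normal-like durations, beta percentages, AHI-derived sub-indices),
  10% per-parameter missingness, lowest SpO₂ anticorrelated with AHI,
  uniform form-version mix, and chronic background comorbidities
  (hyperlipidemia 20%, COPD 15%, GERD 15%) with recurring pre-index
  occurrences and therapy eras persisting through the index date, as chronic
  disease presents in a visit-based EHR. Routine laboratory values
  (triglyceride, blood pressure, GGT) correlate with the comorbidity burden.
* **The planted outcome model** — a logistic model on age, AHI, lowest SpO₂
  and comorbidity count, `logit p = −2.7 + 0.04·(age−50) + 0.025·(AHI−20) +
  0.04·(85−SpO₂min) + 1.0·k`, with `p` the 3-year outcome probability and
  event times exponential at the matching rate, placed in continuous time
  after the test. The comorbidity log-odds of 1.0 (odds ratio ≈ 2.7 per
  major comorbidity) plants genuine non-PSG signal so that the
  all-covariates setting has something real to gain over PSG-only, which is
  the qualitative behavior the feasibility comparison is meant to exhibit;
  observed through the covariates it yields a paired AUC gain of roughly
  +0.02–0.03 at the test-bed scale.

What passing tests on this bed shows: the plumbing is correct (conservation,
linkage, idempotence, leakage-freedom, determinism) and the statistical
machinery behaves (chance-level AUC on permuted labels, recovery of planted
effects, the all-vs-PSG ordering). What it does not show: real-data
performance. The generator draws parameters independently given AHI, has no
scanner drift, no free-text noise, no informative missingness, and its
outcome model is far simpler than cardio-metabolic reality, so absolute AUC
levels here say nothing about any real cohort.

## Numerical conventions and problem sizes

Printed percentages use half-up rounding (one decimal for demographics, two
for outcome rates), matching how the reference tables are typeset; base R's
`round()` would round half to even. Dates are ISO-8601 throughout, and the
delimited CDM read/write pair is the identity on values and row counts.
Deterministic tie-breaks appear wherever an arbitrary choice could leak
nondeterminism: procedure linkage (distance, then date, then id), importance
ranking (value, then name), custom id allocation (catalog order). Degenerate
inputs are defined rather than accidental: empty catalogs yield empty
bundles, an empty CDM yields an all-zero attrition ledger, a single-row
covariate matrix skips variance-based dropping, and a single-class split is
an error, not a warning.

The test suite and the acceptance script run the property suites at 2,000
synthetic persons and 10 seeds per property, with margin-convergence checks
at 4,000 — sizes at which the binomial standard errors are comfortably inside
the asserted tolerances while the whole suite stays fast.

## Known limitations

The pre-existing concept stubs, the 11 form dialects, the cleaning rules,
and the outcome code list all stand in for unavailable supplementary or
licensed material, and are deliberately data-driven so a site can substitute
its own. The attrition and performance numbers of the original feasibility
study depend on restricted hospital data and are out of scope; this package
reproduces the printed arithmetic and the qualitative properties, not the
real-data results. Measurement times of day are not modeled (dates only),
and the CDM writer covers only the tables this pipeline touches.
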