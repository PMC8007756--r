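catalog <- psg_parameter_catalog()
vocab <- build_psg_vocabulary(catalog)

test_that("catalog carries the published structure", {
  expect_equal(nrow(catalog), 86L)
  expect_equal(sum(catalog$domain == "Measurement"), 85L)
  expect_equal(catalog$parameter_name[catalog$domain == "Observation"],
               "Waist/hip ratio")
  expect_equal(sum(catalog$mapping_status == "pre-existing"), 20L)
  expect_equal(sum(catalog$mapping_status == "custom"), 66L)
  counts <- table(catalog$category)
  expect_equal(unname(counts["Respiratory events"]), 16L, ignore_attr = TRUE)
  expect_equal(unname(counts["Multiple sleep latency test"]), 11L,
               ignore_attr = TRUE)
})

test_that("catalog validation rejects malformed catalogs with a diff", {
  dup <- catalog
  dup$parameter_name[2] <- dup$parameter_name[1]
  expect_error(validate_catalog(dup), class = "sleepcdm_catalog_error")

  short <- catalog[-(1:3), ]
  err <- tryCatch(validate_catalog(short), error = identity)
  expect_s3_class(err, "sleepcdm_catalog_error")
  expect_true(any(err$category_diff != 0))
})

test_that("custom concept id allocation is the fixed arithmetic scheme", {
  expect_equal(allocate_custom_concept_id(0), 2000000001)
  expect_equal(allocate_custom_concept_id(65), 2000000066)
  expect_true(all(diff(allocate_custom_concept_id(0:99)) == 1))
  expect_true(all(allocate_custom_concept_id(0:99) >= 2e9))
  expect_error(allocate_custom_concept_id(-1), class = "sleepcdm_vocab_error")
})

test_that("built bundle has the published counts and gapless custom ids", {
  params <- vocab$catalog
  expect_equal(nrow(params), 86L)
  std <- vocab$concept[vocab$concept$concept_id %in%
                         params$standard_concept_id, ]
  expect_equal(sum(std$domain_id == "Measurement"), 85L)
  expect_equal(sum(std$domain_id == "Observation"), 1L)

  custom <- vocab$concept[vocab$concept$vocabulary_id == "PSG Custom", ]
  expect_equal(nrow(custom), 66L)
  expect_true(all(custom$standard_concept == "S"))
  expect_setequal(custom$concept_id, 2000000001 + 0:65)

  panel <- vocab$concept_relationship[
    vocab$concept_relationship$relationship_id %in%
      c("Panel contains", "Contained in panel (LOINC)"), ]
  expect_equal(nrow(panel), 172L)
  maps_to <- vocab$concept_relationship[
    vocab$concept_relationship$relationship_id == "Maps to", ]
  expect_equal(nrow(maps_to), 86L)
  expect_false(anyDuplicated(maps_to$concept_id_1) > 0)
})

test_that("panel relationships come in exact inverse pairs", {
  rel <- vocab$concept_relationship
  pc <- rel[rel$relationship_id == "Panel contains", c(1, 2)]
  cp <- rel[rel$relationship_id == "Contained in panel (LOINC)", c(2, 1)]
  names(cp) <- names(pc)
  expect_equal(dplyr::arrange(pc, concept_id_2),
               dplyr::arrange(cp, concept_id_2))
})

test_that("every custom concept is its own ancestor at level 0", {
  custom_ids <- vocab$catalog$standard_concept_id[
    vocab$catalog$mapping_status == "custom"]
  anc <- vocab$concept_ancestor
  self <- anc[anc$ancestor_concept_id == anc$descendant_concept_id, ]
  expect_setequal(self$ancestor_concept_id, custom_ids)
  expect_true(all(self$min_levels_of_separation == 0))
  expect_true(all(self$max_levels_of_separation == 0))
})

test_that("source codes resolve to bundle concepts of matching domain", {
  ids <- resolve_source_code(catalog$source_code, vocab)
  con <- vocab$concept[match(ids, vocab$concept$concept_id), ]
  expect_equal(con$domain_id, catalog$domain)
  # custom target for an unmapped parameter, stub standard for a mapped one
  expect_gte(resolve_source_code("RDI", vocab), 2e9)
  expect_lt(resolve_source_code("HT", vocab), 2e9)
  expect_error(resolve_source_code("XYZ", vocab),
               class = "sleepcdm_unmapped_code")
})

test_that("empty catalog yields an empty bundle", {
  empty <- build_psg_vocabulary(catalog[0, ])
  expect_equal(nrow(empty$concept), 0L)
  expect_equal(nrow(empty$concept_relationship), 0L)
  expect_equal(nrow(empty$concept_ancestor), 0L)
})

test_that("vocabulary validates and round-trips through OMOP files", {
  expect_equal(nrow(validate_vocabulary(vocab)), 0L)
  dir <- withr::local_tempdir()
  write_vocabulary(vocab, dir)
  expect_true(file.exists(file.path(dir, "CONCEPT.csv")))
  back <- read_vocabulary(dir)
  expect_equal(nrow(back$concept), nrow(vocab$concept))
  expect_equal(back$concept_relationship, vocab$concept_relationship,
               ignore_attr = TRUE)
  expect_equal(nrow(validate_vocabulary(back)), 0L)
})
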