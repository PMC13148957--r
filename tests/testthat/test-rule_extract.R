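test_that("library selection heuristic follows keyword groups, abstains", {
  expect_identical(heuristic_library_selection(
    "libraries prepared with oligo-dT beads"), "polyA")
  expect_identical(heuristic_library_selection(
    "Ribo-Zero depletion was performed"), "inverse rRNA")
  expect_identical(heuristic_library_selection(
    "TruSeq Small RNA kit"), "small RNA")
  expect_identical(heuristic_library_selection(
    "exome capture with RNA Exome probes"), "hybrid selection")
  expect_null(heuristic_library_selection("standard protocol"))
  # precedence: polyA wins over later groups
  expect_identical(heuristic_library_selection(
    "polyA selection after RiboZero failed"), "polyA")
  # keyword must not fire inside a longer word
  expect_null(heuristic_library_selection("polyadenylation signals studied"))
})

test_that("sequencing source heuristic uses explicit synonyms only", {
  expect_identical(heuristic_sequencing_source("scRNA-seq of tumor cells"),
                   "single cell")
  expect_identical(heuristic_sequencing_source(
    "Visium spatial transcriptomics"), "spatial")
  expect_identical(heuristic_sequencing_source("bulk RNA-seq"), "bulk")
  expect_null(heuristic_sequencing_source("RNA-seq of tissue homogenate"))
})

test_that("biopsy type heuristic implements the three-way rule", {
  expect_identical(heuristic_biopsy_type(
    "melanoma tumor tissue with liver metastasis"), "metastasis")
  expect_identical(heuristic_biopsy_type(
    "peripheral blood mononuclear cells from donors"), "blood")
  expect_identical(heuristic_biopsy_type(
    "resected primary melanoma tumor"), "primary")
  # no cancer context established: abstain
  expect_null(heuristic_biopsy_type("healthy skin punch"))
  # explicit hint replaces keyword detection
  expect_identical(heuristic_biopsy_type("resected specimen",
                                         is_cancer_hint = TRUE), "primary")
})

test_that("heuristics never emit labels outside the class's allowed set", {
  texts <- c("oligo dT", "ribodepletion", "GeoMx profiling", "size fraction",
             "10x Chromium run", "bulk tissue", "metastatic melanoma",
             "PBMC sample", "random words only", "")
  for (t in texts) {
    ls <- heuristic_library_selection(t)
    if (!is.null(ls)) {
      expect_true(ls %in% test_registry$library_selection$allowed_values)
    }
    ss <- heuristic_sequencing_source(t)
    if (!is.null(ss)) {
      expect_true(ss %in% test_registry$sequencing_source$allowed_values)
    }
    bt <- heuristic_biopsy_type(t)
    if (!is.null(bt)) {
      expect_true(bt %in% test_registry$biopsy_type$allowed_values)
    }
  }
})

test_that("cross-source check prefers agreement, flags conflicts", {
  organ <- test_registry$organ
  agree <- cross_source_check(
    list(list(value = "lung", source = "sra_xml"),
         list(value = "Lung", source = "biosample")), organ)
  expect_identical(agree$status, "validated")
  expect_identical(agree$values, "lung")

  conflict <- cross_source_check(
    list(list(value = "lung", source = "sra_xml"),
         list(value = "liver", source = "biosample")), organ)
  expect_identical(conflict$status, "flagged")
  expect_setequal(conflict$values, c("lung", "liver"))
  expect_match(conflict$notes, "organ:")
  expect_match(conflict$notes, "sra_xml")

  single <- cross_source_check(
    list(list(value = "lung", source = "biosample")), organ)
  expect_identical(single$status, "validated")

  # invalid single-source candidate is rejected to missing
  bad <- cross_source_check(
    list(list(value = "fibroblast", source = "biosample")),
    test_registry$age)
  expect_identical(bad$status, "missing")
})

test_that("rule stage fills API classes, extracts aliases, propagates", {
  rec <- tiny_record()
  rec$api_fields <- c(study_accession = "PRJNA1", platform = "ILLUMINA",
                      bases = "1000000", library_strategy = "RNA-Seq")
  rec$biosample_attributes <- c(sex = "female", age = "fibroblast",
                                `cell line` = "hela")
  row <- run_rule_stage(rec, lexicons = test_lexicons,
                        registry = test_registry)
  expect_identical(row$classes$study_accession$source, "api")
  expect_identical(row$classes$instrument_platform$values, "ILLUMINA")
  expect_identical(row$classes$sex$values, "female")
  expect_identical(row$classes$sex$source, "rule")
  # implausible age rejected, stays missing... but then filled by the
  # recognized cell line's registry age
  expect_identical(row$classes$cell_line$values, "HeLa")
  expect_identical(row$classes$age$source, "lexicon_propagation")
  expect_identical(row$classes$age$values, "31")
  # organ propagated and ontology-normalized
  expect_identical(row$classes$organ$values, "uterine cervix")
  expect_true(any(grepl("^UBERON", row$classes$organ$ids)))
})

test_that("rule stage is deterministic and validation-clean", {
  pool <- generate_pool(6, seed = 21, lexicons = test_lexicons)
  dir <- withr::local_tempdir()
  write_fixture_dir(pool, dir)
  fetcher <- fixture_fetcher(dir)
  for (s in pool[1:3]) {
    rec <- fetch_run_record(s$run_accession, fetcher)
    r1 <- run_rule_stage(rec, lexicons = test_lexicons,
                         registry = test_registry)
    r2 <- run_rule_stage(rec, lexicons = test_lexicons,
                         registry = test_registry)
    expect_identical(r1, r2)
    # no stored value violates its validation contract
    for (cn in names(r1$classes)) {
      slot <- r1$classes[[cn]]
      if (slot$status != "validated") next
      for (v in slot$values) {
        out <- validate_value(test_registry[[cn]], v)
        expect_true(out$accepted, label = paste(cn, v))
      }
    }
  }
})

test_that("explicit plants are recovered and plant-free fixtures stay empty", {
  pool <- generate_pool(12, seed = 33, lexicons = test_lexicons)
  dir <- withr::local_tempdir()
  write_fixture_dir(pool, dir)
  fetcher <- fixture_fetcher(dir)
  for (s in pool[1:6]) {
    rec <- fetch_run_record(s$run_accession, fetcher)
    row <- run_rule_stage(rec, lexicons = test_lexicons,
                          registry = test_registry)
    for (cls in names(s$mode)[s$mode == "explicit"]) {
      slot <- row$classes[[cls]]
      expect_false(slot$status == "missing",
                   label = paste(s$run_accession, cls))
      ok <- hybrid_match(slot$values, s$truth[[cls]], test_registry[[cls]],
                         test_lexicons)
      # propagation may override only classes the truth left elsewhere;
      # alias-extracted plants themselves must match
      if (slot$source == "rule") {
        expect_true(ok, label = paste(s$run_accession, cls))
      }
    }
  }
  # plant-free: no rule extraction at all beyond API-direct fields
  blank <- sample_all_absent()
  write_fixture_dir(list(blank), dir2 <- withr::local_tempdir())
  rec <- fetch_run_record(blank$run_accession, fixture_fetcher(dir2))
  row <- run_rule_stage(rec, lexicons = test_lexicons,
                        registry = test_registry)
  for (cn in names(llm_routed_classes(test_registry))) {
    expect_identical(row$classes[[cn]]$status, "missing", label = cn)
  }
})
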