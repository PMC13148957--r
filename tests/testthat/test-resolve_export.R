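make_prediction <- function(cls, values, ppl = 1.5) {
  structure(list(class_name = cls, values = values,
                 confidence = structure(list(mean_nll = log(ppl), ppl = ppl),
                                        class = "confidence"),
                 raw_text = paste(values, collapse = ", "),
                 flags = character(0)), class = "prediction")
}

test_that("locked policy keeps validated rule values, fills gaps", {
  row <- annotation_row("SRR1", test_registry)
  row <- sramend:::set_annotation(row, "organ", "lung", "rule", "validated")
  preds <- list(make_prediction("organ", "liver"),
                make_prediction("disease", "melanoma"),
                make_prediction("sex", "unknown"))
  out <- resolve_row(row, preds, policy = "locked", registry = test_registry)
  expect_identical(out$classes$organ$values, "lung")      # locked
  expect_identical(out$classes$organ$alt, "liver")        # loser retained
  expect_identical(out$classes$disease$values, "melanoma")
  expect_identical(out$classes$disease$source, "llm")     # fill-missing
  expect_identical(out$classes$sex$status, "missing")     # unknown never fills
})

test_that("per-class preference lets the preferred source win", {
  row <- annotation_row("SRR1", test_registry)
  row <- sramend:::set_annotation(row, "organ", "lung", "rule", "validated")
  row <- sramend:::set_annotation(row, "library_selection", "polyA", "rule",
                                  "validated")
  preds <- list(make_prediction("organ", "liver"),
                make_prediction("library_selection", "other"))
  out <- resolve_row(row, preds, policy = "per_class_preference",
                     registry = test_registry)
  # organ prefers the model; the rule value is preserved as alternative
  expect_identical(out$classes$organ$values, "liver")
  expect_identical(out$classes$organ$alt, "lung")
  # library selection prefers the rule
  expect_identical(out$classes$library_selection$values, "polyA")
  expect_identical(out$classes$library_selection$alt, "other")
})

test_that("under locked policy no validated rule value is ever displaced", {
  pool <- generate_pool(10, seed = 13, lexicons = test_lexicons)
  dir <- withr::local_tempdir()
  write_fixture_dir(pool, dir)
  fetcher <- fixture_fetcher(dir)
  bk <- mock_backend(truth_table(pool), test_registry,
                     substitution_rate = 0.5, abstention_rate = 0.2,
                     seed = 8L)
  for (s in pool[1:5]) {
    rec <- fetch_run_record(s$run_accession, fetcher)
    curated <- run_rule_stage(rec, lexicons = test_lexicons,
                              registry = test_registry)
    bundle <- build_context(rec)
    preds <- infer_run(bk, s$run_accession, bundle, test_registry)
    out <- resolve_row(curated, preds, policy = "locked",
                       registry = test_registry)
    for (cn in names(curated$classes)) {
      if (curated$classes[[cn]]$status == "validated") {
        expect_identical(out$classes[[cn]]$values,
                         curated$classes[[cn]]$values,
                         label = paste(s$run_accession, cn))
      }
    }
  }
})

test_that("post-hoc propagation normalizes model cell lines and diseases", {
  row <- annotation_row("SRR1", test_registry)
  row <- sramend:::set_annotation(row, "cell_line", "hela", "llm",
                                  "validated")
  row <- sramend:::set_annotation(row, "disease", "TB", "llm", "validated")
  out <- post_propagate(row, test_lexicons)
  expect_identical(out$classes$cell_line$values, "HeLa")
  # disease already present: never overwritten by propagation, but
  # normalized to the preferred ontology name with its ID
  expect_identical(out$classes$disease$values, "tuberculosis")
  expect_identical(out$classes$disease$ids, "DOID:399")
  # dependent fields filled from the line's registry entry
  expect_identical(out$classes$organ$values, "uterine cervix")
  expect_identical(out$classes$organ$source, "lexicon_propagation")
  # identity when nothing new
  expect_identical(post_propagate(out, test_lexicons), out)
})

test_that("exports round-trip identically for csv, tsv and json", {
  row1 <- annotation_row("SRR1", test_registry)
  row1 <- sramend:::set_annotation(row1, "organ", "lung", "rule", "validated",
                                   ids = "UBERON:0002048")
  row1 <- sramend:::set_annotation(
    row1, "disease", "melanoma", "llm", "validated",
    confidence = structure(list(mean_nll = 0.5, ppl = exp(0.5)),
                           class = "confidence"))
  row2 <- annotation_row("SRR2", test_registry)
  row3 <- annotation_row("SRR3", test_registry)
  row3 <- sramend:::set_annotation(row3, "sex", "male", "rule", "validated")
  rows <- list(row1, row2, row3)

  prefix <- file.path(withr::local_tempdir(), "out")
  paths <- export_table(rows, formats = c("csv", "tsv", "json"),
                        path_prefix = prefix)
  expect_named(paths, c("csv", "tsv", "json"))

  tsv <- read_exported_table(paths[["tsv"]])
  expect_identical(nrow(tsv), 3L)
  expect_length(intersect(names(test_registry), names(tsv)), 19L)

  canon <- function(df) {
    df <- df[, sort(names(df))]
    m <- vapply(df, function(col) {
      ch <- as.character(col)
      ch[is.na(ch)] <- ""
      ch
    }, character(nrow(df)))
    rownames(m) <- NULL
    m
  }
  ref <- canon(rows_to_data_frame(rows))
  for (fmt in c("csv", "tsv", "json")) {
    got <- canon(read_exported_table(paths[[fmt]]))
    expect_identical(dim(got), dim(ref), label = fmt)
    # numeric cells may re-render; compare with numeric tolerance fallback
    same <- got == ref
    if (!all(same)) {
      num_ref <- suppressWarnings(as.numeric(ref[!same]))
      num_got <- suppressWarnings(as.numeric(got[!same]))
      expect_true(all(!is.na(num_ref) & !is.na(num_got) &
                        abs(num_ref - num_got) < 1e-9), label = fmt)
    }
  }
  # requesting a format without its capability names the available ones
  expect_error(export_table(rows, formats = "xlsx", path_prefix = prefix),
               "available")
})

test_that("table summaries count fill rates and confidence quantiles", {
  rows <- lapply(1:4, function(i) annotation_row(paste0("SRR", i),
                                                 test_registry))
  for (i in 1:3) {
    rows[[i]] <- sramend:::set_annotation(
      rows[[i]], "organ", "lung", "rule", "validated",
      confidence = structure(list(mean_nll = log(i), ppl = i),
                             class = "confidence"))
  }
  rows[[4]] <- sramend:::set_annotation(
    rows[[4]], "organ", "liver", "llm", "validated",
    confidence = structure(list(mean_nll = log(4), ppl = 4),
                           class = "confidence"))
  s <- summarize_table(rows, test_registry)
  expect_identical(unname(s$fill_rates[["organ"]]), 1)
  expect_identical(unname(s$fill_rates[["is_cancer"]]), 0)
  # median of ppl {1,2,3,4}: independent middle-pair average
  ppls <- c(1, 2, 3, 4)
  expect_equal(unname(s$ppl_quantiles[["50%"]]),
               mean(sort(ppls)[2:3]), tolerance = 1e-12)
  # 3-of-4 fill rate
  rows[[4]] <- annotation_row("SRR4", test_registry)
  rows[[4]] <- sramend:::set_annotation(rows[[4]], "disease", "melanoma",
                                        "rule", "validated")
  s2 <- summarize_table(rows, test_registry)
  expect_identical(unname(s2$fill_rates[["organ"]]), 0.75)
})
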