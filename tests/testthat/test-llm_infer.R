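test_that("prompts carry the four blocks and exactly one class definition", {
  bundle <- make_bundle("Biopsy of a melanoma patient.",
                        notes = "organ: source sra_xml says 'skin'")
  p <- build_prompt("SRR1", bundle, test_registry$is_cancer)
  txt <- format(p)
  expect_match(txt, "^Run accession: SRR1")
  expect_match(txt, "Context summary: Biopsy of a melanoma patient")
  expect_match(txt, "- is_cancer: ", fixed = TRUE)
  expect_match(txt, "return\\s+\"unknown\"")
  expect_match(txt, "\",\" or \";\" separator", fixed = FALSE)
  # only its own definition line
  expect_no_match(txt, "- organ: ")
  # blocks appear in order (a) < (b) < (c) < (d)
  pos <- c(regexpr("Run accession", txt), regexpr("Context summary", txt),
           regexpr("- is_cancer", txt), regexpr("Extract information", txt))
  expect_true(all(diff(pos) > 0))
  # API-direct classes are never prompted
  expect_error(build_prompt("SRR1", bundle, test_registry$study_accession),
               "API-direct")
})

test_that("prompts for different classes differ only in the definition block", {
  bundle <- make_bundle("Liver tissue from a donor.")
  classes <- llm_routed_classes(test_registry)
  prompts <- lapply(classes, function(cls) build_prompt("SRR9", bundle, cls))
  base <- prompts[[1]]
  for (p in prompts[-1]) {
    expect_identical(p$run_accession, base$run_accession)
    expect_identical(p$summary_text, base$summary_text)
    expect_identical(p$instruction_block, base$instruction_block)
    expect_false(identical(p$class_definition_line,
                           base$class_definition_line))
  }
})

test_that("adapter routing is a pure per-class lookup with base fallback", {
  cfg <- list(adapter_map = c(organ = "adapter_organ"),
              base_model = "mistral-base")
  expect_identical(route_adapter(test_registry$organ, cfg), "adapter_organ")
  expect_identical(route_adapter(test_registry$sex, cfg), "mistral-base")
  expect_identical(route_adapter(test_registry$sex, list()), "base")
  expect_error(route_adapter(test_registry$study_accession, cfg),
               "not routed")
})

test_that("confidence is mean NLL with perplexity as its exponential", {
  c0 <- confidence_from_logprobs(c(0, 0, 0))
  expect_identical(c0$mean_nll, 0)
  expect_identical(c0$ppl, 1)
  c1 <- confidence_from_logprobs(-log(2))
  expect_equal(c1$mean_nll, log(2), tolerance = 1e-12)
  expect_equal(c1$ppl, 2, tolerance = 1e-12)
  # arithmetic mean then exponentiation: frozen against direct computation
  c2 <- confidence_from_logprobs(c(-1, -3))
  expect_equal(c2$mean_nll, 2, tolerance = 1e-12)
  expect_equal(c2$ppl, 7.3890560989306495, tolerance = 1e-12)
  # invariant over random inputs
  set.seed(11)
  for (i in 1:30) {
    lp <- -stats::rexp(sample(1:10, 1))
    cf <- confidence_from_logprobs(lp)
    expect_equal(cf$ppl, exp(cf$mean_nll), tolerance = 1e-9)
    expect_gte(cf$mean_nll, 0)
    expect_gte(cf$ppl, 1)
  }
  expect_error(confidence_from_logprobs(numeric(0)), "non-empty")
  expect_error(confidence_from_logprobs(c(-1, 0.5)), "<= 0")
})

test_that("prediction parsing snaps labels, splits values, handles failure", {
  fake_backend <- function(answer) {
    structure(list(generate = function(prompt) {
      list(text = answer, logprobs = c(-0.1, -0.2))
    }, model_name = "fake", adapter_id = "fake"), class = "backend")
  }
  bundle <- make_bundle("ctx")
  p_org <- build_prompt("SRR1", bundle, test_registry$organ)
  p_lib <- build_prompt("SRR1", bundle, test_registry$library_selection)
  p_can <- build_prompt("SRR1", bundle, test_registry$is_cancer)

  pred <- infer_class(fake_backend("polyA"), p_lib,
                      test_registry$library_selection)
  expect_identical(pred$values, "polyA")

  pred2 <- infer_class(fake_backend("lung, Liver"), p_org,
                       test_registry$organ)
  expect_identical(pred2$values, c("lung", "Liver"))

  pred3 <- infer_class(fake_backend("maybe-cancer"), p_can,
                       test_registry$is_cancer)
  expect_identical(pred3$values, "unknown")
  expect_match(pred3$flags, "unparseable_label")

  # case-insensitive snap to canonical label casing
  pred4 <- infer_class(fake_backend(" \"TRUE\" "), p_can,
                       test_registry$is_cancer)
  expect_identical(pred4$values, "True")

  # unknown never co-occurs with real values
  pred5 <- infer_class(fake_backend("lung, unknown"), p_org,
                       test_registry$organ)
  expect_identical(pred5$values, "lung")

  # backend failure degrades to flagged unknown
  dead <- structure(list(generate = function(prompt) stop("boom")),
                    class = "backend")
  pred6 <- infer_class(dead, p_org, test_registry$organ)
  expect_identical(pred6$values, "unknown")
  expect_identical(pred6$flags, "backend_failure")
})

test_that("mock backend answers from truth deterministically", {
  truth <- list(SRR1 = list(organ = "lung", is_cancer = "True"))
  bk <- mock_backend(truth, test_registry, seed = 4L)
  bundle <- make_bundle("ctx")
  p <- build_prompt("SRR1", bundle, test_registry$organ)
  a1 <- bk$generate(p)
  a2 <- bk$generate(p)
  expect_identical(a1, a2)
  expect_identical(a1$text, "lung")
  # unknown for classes without truth
  p2 <- build_prompt("SRR1", bundle, test_registry$treatment)
  expect_identical(bk$generate(p2)$text, "unknown")
  # marker-string input parses to the same answers
  bk2 <- mock_backend(list(SRR1 = "organ=lung;;is_cancer=True"),
                      test_registry, seed = 4L)
  expect_identical(bk2$generate(p)$text, "lung")
})

test_that("per-run prediction files hold all 15 classes and round-trip", {
  truth <- list(SRR5 = list(organ = "lung"))
  bk <- mock_backend(truth, test_registry, seed = 2L)
  bundle <- make_bundle("ctx for SRR5")
  preds <- infer_run(bk, "SRR5", bundle, test_registry)
  expect_length(preds, 15L)
  path <- withr::local_tempfile(fileext = ".json")
  write_prediction_file("SRR5", preds, path, test_registry)
  back <- read_prediction_file(path)
  expect_identical(back$run_accession, "SRR5")
  expect_length(back$predictions, 15L)
  for (nm in names(preds)) {
    expect_identical(back$predictions[[nm]]$values, preds[[nm]]$values)
    expect_equal(back$predictions[[nm]]$confidence$ppl,
                 preds[[nm]]$confidence$ppl, tolerance = 1e-12)
  }
  # missing a class is a contract violation
  expect_error(write_prediction_file("SRR5", preds[-1], path, test_registry),
               "missing")
})
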