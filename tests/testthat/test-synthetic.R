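test_that("generated pools are seed-deterministic and balanced within one", {
  lex <- test_lexicons
  cfg <- generation_config(lex)
  p1 <- generate_pool(100, classes = c("sequencing_source", "organ"),
                      seed = 17, config = cfg, lexicons = lex)
  p2 <- generate_pool(100, classes = c("sequencing_source", "organ"),
                      seed = 17, config = cfg, lexicons = lex)
  expect_identical(p1, p2)
  p3 <- generate_pool(100, classes = c("sequencing_source", "organ"),
                      seed = 18, config = cfg, lexicons = lex)
  expect_false(identical(p1, p3))

  # balance within each tier: counts differ by at most 1 per label
  tiers <- vapply(p1, `[[`, character(1), "tier")
  for (tier in unique(tiers)) {
    labs <- vapply(p1[tiers == tier], function(s) s$truth$sequencing_source,
                   character(1))
    counts <- table(labs)
    expect_setequal(names(counts), c("bulk", "single cell", "spatial",
                                     "unknown"))
    expect_lte(max(counts) - min(counts), 1L)
  }
})

test_that("phrasing modes behave as declared", {
  lex <- test_lexicons
  pool <- generate_pool(60, seed = 23, lexicons = lex)
  for (s in pool[1:20]) {
    for (cls in names(s$mode)) {
      tr <- s$truth[[cls]]
      if (s$mode[[cls]] == "absent") {
        expect_identical(tr, "unknown")
      } else if (s$mode[[cls]] == "explicit") {
        # value stated with its class keyword
        expect_match(s$context_text,
                     paste0("The ", gsub("_", " ", cls), " recorded"),
                     fixed = FALSE)
      }
    }
    # hidden marker round-trips the truth
    expect_identical(parse_hidden_marker(s$hidden_marker), s$truth)
  }
  # paraphrase of an anatomy value uses the lexicon synonym
  cfg <- generation_config(lex)
  sent <- sramend:::render_class_sentence("organ", "oral cavity",
                                          "paraphrase", lex)
  expect_match(sent, "mouth")
  expect_no_match(sent, "oral cavity")
})

test_that("fixture XML embeds plants consistently with modes", {
  pool <- generate_pool(5, seed = 29, lexicons = test_lexicons)
  for (s in pool) {
    fx <- render_fixture_xml(s)
    attrs <- parse_biosample_xml(fx$biosample_xml)
    for (cls in names(s$mode)) {
      key <- gsub("_", " ", cls)
      if (s$mode[[cls]] == "explicit") {
        expect_true(key %in% names(attrs), label = key)
        expect_identical(unname(attrs[[key]]),
                         paste(s$truth[[cls]], collapse = "; "))
      } else {
        expect_false(key %in% names(attrs), label = key)
      }
    }
    rec <- parse_run_xml(fx$run_xml)
    expect_identical(rec$study_fields[["study_abstract"]], s$context_text)
  }
})

test_that("proximity split cuts the pool into ordered, exhaustive tiers", {
  lex <- test_lexicons
  cfg <- generation_config(lex)
  pool <- generate_pool(100, seed = 41, config = cfg, lexicons = lex)
  ref <- generate_pool(30, seed = 42, config = cfg, lexicons = lex,
                       reference = TRUE)
  splits <- split_by_proximity(pool, ref, sizes = c(20, 60, 20))
  expect_identical(vapply(splits, length, integer(1)),
                   c(ID = 20L, MID = 60L, OOD = 20L))
  ids <- unname(unlist(lapply(splits, function(p) {
    vapply(p, `[[`, character(1), "sample_id")
  })))
  expect_identical(sort(ids),
                   sort(vapply(pool, `[[`, character(1), "sample_id")))
  # mean similarity monotone ID >= MID >= OOD
  sc <- attr(splits, "scores")
  expect_gte(mean(sc[1:20]), mean(sc[21:80]))
  expect_gte(mean(sc[21:80]), mean(sc[81:100]))
  # size mismatch is an error
  expect_error(split_by_proximity(pool, ref, sizes = c(10, 10, 10)),
               "sum\\(sizes\\)")
})

test_that("split ranking respects scores and breaks ties by id", {
  mk <- function(id, text) {
    structure(list(sample_id = id, run_accession = id, context_text = text,
                   truth = list(), mode = character(0), tier = "ID",
                   split = NA_character_, hidden_marker = ""),
              class = "synthetic_sample")
  }
  ref <- list(mk("R1", "alpha beta gamma delta"))
  pool <- list(mk("S1", "alpha beta gamma delta"),   # sim 1
               mk("S2", "alpha beta zzz qqq"),       # middle
               mk("S3", "totally different words"))  # sim 0
  sp <- split_by_proximity(pool, ref, sizes = c(1, 1, 1))
  expect_identical(sp$ID[[1]]$sample_id, "S1")
  expect_identical(sp$MID[[1]]$sample_id, "S2")
  expect_identical(sp$OOD[[1]]$sample_id, "S3")
  # all-equal scores: deterministic assignment by id order
  pool_eq <- list(mk("S3", "same text"), mk("S1", "same text"),
                  mk("S2", "same text"))
  sp_eq <- split_by_proximity(pool_eq, list(mk("R1", "same text")),
                              sizes = c(1, 1, 1))
  expect_identical(sp_eq$ID[[1]]$sample_id, "S1")
  expect_identical(sp_eq$OOD[[1]]$sample_id, "S3")
})

test_that("leakage diagnostics count near-duplicates and pool overlaps", {
  mk <- function(id, text, organ) {
    structure(list(sample_id = id, run_accession = id, context_text = text,
                   truth = list(organ = organ), mode = c(organ = "explicit"),
                   tier = "ID", split = NA_character_, hidden_marker = ""),
              class = "synthetic_sample")
  }
  splits <- list(ID = list(mk("a", "identical words here", "lung")),
                 OOD = list(mk("b", "identical words here", "lung")))
  lc <- leakage_check(splits, threshold = 0.9)
  expect_gte(lc$near_duplicates, 1L)
  expect_identical(lc$pool_violations, "organ=lung")

  splits2 <- list(ID = list(mk("a", "first text entirely", "lung")),
                  OOD = list(mk("b", "second wording altogether", "liver")))
  lc2 <- leakage_check(splits2, threshold = 1.0)
  expect_identical(lc2$near_duplicates, 0L)
  expect_length(lc2$pool_violations, 0L)

  # generator pools are disjoint across recovered splits by construction
  lex <- test_lexicons
  cfg <- generation_config(lex)
  pool <- generate_pool(100, seed = 51, config = cfg, lexicons = lex)
  ref <- generate_pool(30, seed = 52, config = cfg, lexicons = lex,
                       reference = TRUE)
  sp <- split_by_proximity(pool, ref, sizes = c(20, 60, 20))
  lc3 <- leakage_check(sp, threshold = 0.95)
  expect_length(lc3$pool_violations, 0L)
})
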