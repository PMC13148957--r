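#' Default configuration for the synthetic benchmark generator
#'
#' The generator emulates the pipeline's input space offline: labeled
#' paragraph contexts (and SRA-like XML fixtures) in which each class's
#' information is stated explicitly, paraphrased through a synonym or
#' indirect cue, or absent. Labels are balanced per class including
#' "unknown"; open-vocabulary value pools are partitioned across the
#' reference (train-like) set and the ID/MID/OOD test tiers so that no
#' open-vocabulary value is shared between splits; each tier carries its
#' own protocol boilerplate whose token overlap with the reference tier
#' decreases from ID to OOD, giving the proximity structure the splitter
#' recovers.
#'
#' @param lexicons A `lexicon_set` supplying value pools and synonyms.
#' @return A `generation_config` list: `label_pools`, `vocab_groups`,
#'   `mode_proportions`, `tier_proportions`, `boilerplate`.
#' @export
generation_config <- function(lexicons = load_lexicons()) {
  anat <- vapply(lexicons$anatomy_map$entries, `[[`, character(1),
                 "preferred_name")
  dis <- vapply(lexicons$disease_map$entries, `[[`, character(1),
                "preferred_name")
  cells <- names(lexicons$cell_lines)
  cell_types <- c("fibroblast", "neuron", "melanocyte", "hepatocyte",
                  "monocyte", "keratinocyte", "astrocyte", "osteoblast",
                  "cardiomyocyte", "lymphoblast", "erythrocyte",
                  "chondrocyte")
  treatments <- c("cisplatin", "vemurafenib", "doxorubicin", "paclitaxel",
                  "nivolumab", "radiotherapy", "tamoxifen", "imatinib",
                  "gemcitabine", "dexamethasone", "metformin", "surgery")
  treatment_times <- c("pre-treatment", "post-treatment", "on treatment",
                       "day 3", "week 2", "month 1", "baseline",
                       "follow-up")
  ethnicities <- c("caucasian", "asian", "black", "hispanic",
                   "african american", "south asian", "east asian",
                   "middle eastern")
  ages <- c("8", "16", "34", "47", "52", "67", "73", "child", "teen",
            "adult", "senior")

  partition4 <- function(values) {
    groups <- rep(c("train_ref", "ID", "MID", "OOD"),
                  length.out = length(values))
    split(values, groups)
  }

  list(
    label_pools = list(
      library_selection = c("polyA", "inverse rRNA", "hybrid selection",
                            "small RNA", "other"),
      sequencing_source = c("bulk", "single cell", "spatial"),
      biopsy_type = c("primary", "metastasis", "blood"),
      response = c("no treatment", "stable", "progressive", "success"),
      is_cancer = c("True", "False"),
      sex = c("male", "female"),
      age = ages
    ),
    vocab_groups = list(
      organ = partition4(anat),
      biopsy_site = partition4(rev(anat)),
      disease = partition4(dis),
      cell_line = partition4(cells),
      cell_type = partition4(cell_types),
      treatment = partition4(treatments),
      treatment_time = partition4(treatment_times),
      ethnicity = partition4(ethnicities)
    ),
    mode_proportions = c(explicit = 0.6, paraphrase = 0.4),
    tier_proportions = c(ID = 0.2, MID = 0.6, OOD = 0.2),
    boilerplate = list(
      train_ref = paste(
        "Libraries were prepared following the standard institutional",
        "protocol and sequenced on an Illumina NovaSeq 6000 instrument with",
        "paired end chemistry, after quality control of extracted total RNA",
        "with a Bioanalyzer and quantification on a Qubit fluorometer.",
        "Sequencing pools passed vendor quality thresholds, were",
        "demultiplexed with the default pipeline and checked against",
        "internal spike in controls before downstream analysis."),
      ID = paste(
        "Libraries were prepared following the standard institutional",
        "protocol and sequenced on an Illumina NovaSeq 6000 instrument with",
        "paired end chemistry, after quality control of extracted total RNA",
        "with a Bioanalyzer and quantification on a Qubit fluorometer.",
        "Sequencing pools passed vendor quality thresholds, were",
        "demultiplexed with the default pipeline and checked against",
        "internal spike in controls before downstream analysis."),
      MID = paste(
        "Libraries were prepared following the standard institutional",
        "protocol and sequenced on an Illumina NovaSeq 6000 instrument with",
        "paired end chemistry, after quality control of extracted total RNA.",
        "Read level curation relied on custom scripts maintained by the",
        "submitting laboratory, combining adapter removal and alignment",
        "summaries into periodic reports."),
      OOD = paste(
        "Specimens underwent an alternative bench preparation route before",
        "nanopore long read profiling; basecalling relied on a community",
        "maintained neural basecaller and adapters were trimmed with a",
        "third party utility. Molecule level duplicate collapsing, coverage",
        "smoothing and signal drift compensation happened inside a",
        "containerized environment orchestrated by workflow descriptors.")
    )
  )
}

# Indirect cues used in paraphrase mode for closed classes (open-vocabulary
# classes paraphrase through lexicon synonyms instead). Cues for labels the
# printed extraction rules require to be explicit (metastasis, blood) keep
# the triggering keyword, mirroring how such samples read in SRA.
.paraphrase_cues <- list(
  library_selection = c(
    "polyA" = "Transcripts were enriched with oligo-dT beads.",
    "inverse rRNA" = "Ribosomal RNA was removed with a Ribo-Zero kit.",
    "hybrid selection" = "Targets were pulled down by exon capture probes.",
    "small RNA" = "Short transcripts were isolated by size fractionation.",
    "other" = "A custom enrichment chemistry was applied to the libraries."),
  sequencing_source = c(
    "bulk" = "Aggregate RNA from a homogenized cell mixture was profiled.",
    "single cell" = "Individual cells were captured in droplets and profiled one by one.",
    "spatial" = "Profiling preserved in-tissue localization of transcripts."),
  biopsy_type = c(
    "primary" = "Material was resected at the original tumor site.",
    "metastasis" = "Material came from metastatic spread to a distant organ.",
    "blood" = "The specimen was collected as a peripheral blood draw."),
  response = c(
    "no treatment" = "The donor received no therapy before collection.",
    "stable" = "Under therapy the lesion neither grew nor shrank.",
    "progressive" = "The lesion continued to grow despite therapy.",
    "success" = "Therapy achieved a complete remission."),
  is_cancer = c(
    "True" = "The donor carried an oncology diagnosis at collection.",
    "False" = "The donor was a disease free volunteer."),
  sex = c(
    "male" = "The donor was a man.",
    "female" = "The donor was a woman."),
  age = character(0)
)

#' Generate a pool of labeled synthetic samples
#'
#' Per tier and class, labels (including "unknown") are assigned balanced —
#' counts differ by at most one — then shuffled. A sample whose label for a
#' class is "unknown" omits that class from the text (mode `absent`); other
#' samples draw `explicit` or `paraphrase` mode from the configured
#' proportions. Explicit mode states the value with its class keyword;
#' paraphrase mode uses a lexicon synonym or an indirect cue. Deterministic
#' given the seed.
#'
#' @param n Pool size (> 0).
#' @param classes Class names to cover; default: all model-routed classes.
#' @param seed Integer seed.
#' @param config A [generation_config()].
#' @param lexicons A `lexicon_set`.
#' @param reference Generate a train-like reference pool (single tier
#'   `train_ref` drawing on the reference vocabulary group).
#' @param accession_prefix Prefix for generated run accessions.
#' @return List of `synthetic_sample`s.
#' @export
generate_pool <- function(n, classes = NULL, seed = 1L,
                          config = NULL, lexicons = load_lexicons(),
                          reference = FALSE,
                          accession_prefix = if (reference) "SRR77" else "SRR88") {
  stopifnot(n > 0)
  if (is.null(config)) config <- generation_config(lexicons)
  registry <- class_registry()
  if (is.null(classes)) classes <- names(llm_routed_classes(registry))
  open_vocab <- names(config$vocab_groups)
  for (cls in intersect(classes, open_vocab)) {
    pools <- config$vocab_groups[[cls]]
    if (!length(unlist(pools))) {
      stop("empty value pool configured for open-vocabulary class ", cls)
    }
  }

  with_seed(seed, {
    tiers <- if (reference) {
      rep("train_ref", n)
    } else {
      props <- config$tier_proportions
      counts <- round(props * n)
      counts[length(counts)] <- n - sum(counts[-length(counts)])
      rep(names(props), times = counts)
    }
    # labels balanced within tier
    labels <- list()
    modes <- list()
    for (cls in classes) {
      lab <- character(n)
      for (tier in unique(tiers)) {
        idx <- which(tiers == tier)
        pool <- if (cls %in% open_vocab) {
          config$vocab_groups[[cls]][[tier]]
        } else {
          config$label_pools[[cls]]
        }
        pool <- unique(c(pool, "unknown"))
        lab[idx] <- sample(rep_len(pool, length(idx)))
      }
      labels[[cls]] <- lab
      mp <- config$mode_proportions / sum(config$mode_proportions)
      m <- ifelse(lab == "unknown", "absent",
                  sample(names(mp), n, replace = TRUE, prob = mp))
      modes[[cls]] <- m
    }

    lapply(seq_len(n), function(i) {
      tier <- tiers[[i]]
      truth <- lapply(classes, function(cls) labels[[cls]][[i]])
      names(truth) <- classes
      mode <- vapply(classes, function(cls) modes[[cls]][[i]], character(1))
      sentences <- c(
        "Transcriptome study of human samples.",
        config$boilerplate[[tier]]
      )
      for (cls in classes) {
        if (mode[[cls]] == "absent") next
        sentences <- c(sentences,
                       render_class_sentence(cls, truth[[cls]], mode[[cls]],
                                             lexicons))
      }
      acc <- sprintf("%s%05d", accession_prefix, i)
      structure(list(
        sample_id = acc,
        run_accession = acc,
        context_text = paste(sentences, collapse = " "),
        truth = truth,
        mode = mode,
        tier = tier,
        split = NA_character_,
        hidden_marker = make_hidden_marker(truth)
      ), class = "synthetic_sample")
    })
  })
}

# One sentence stating (explicit) or hinting at (paraphrase) a class value.
render_class_sentence <- function(cls, value, mode, lexicons) {
  label <- gsub("_", " ", cls)
  if (mode == "explicit") {
    return(sprintf("The %s recorded for this run is %s.", label, value))
  }
  # paraphrase: lexicon synonym for open-vocabulary values, cue otherwise
  cues <- .paraphrase_cues[[cls]]
  if (!is.null(cues) && value %in% names(cues)) {
    return(unname(cues[[value]]))
  }
  syn <- paraphrase_synonym(cls, value, lexicons)
  if (cls == "cell_line") {
    return(sprintf("Cultures of %s were expanded before extraction.", syn))
  }
  sprintf("The material under study involved %s.", syn)
}

paraphrase_synonym <- function(cls, value, lexicons) {
  map <- switch(cls,
    disease = lexicons$disease_map,
    organ = , biopsy_site = lexicons$anatomy_map,
    NULL)
  if (!is.null(map)) {
    for (e in map$entries) {
      if (identical(e$preferred_name, value) && length(e$synonyms)) {
        return(e$synonyms[[1]])
      }
    }
  }
  if (cls == "cell_line") {
    entry <- lexicons$cell_lines[[value]]
    if (!is.null(entry) && length(entry$synonyms)) return(entry$synonyms[[1]])
  }
  value
}

make_hidden_marker <- function(truth) {
  paste(vapply(names(truth), function(cls) {
    paste0(cls, "=", paste(truth[[cls]], collapse = "|"))
  }, character(1)), collapse = ";;")
}

#' Parse a machine-readable truth marker
#'
#' Inverse of the marker written by [generate_pool()]:
#' `"organ=lung;;sex=male"` becomes `list(organ = "lung", sex = "male")`.
#' Multi-valued truths are `|`-separated.
#'
#' @param marker Marker string.
#' @return Named list class -> character vector.
#' @export
parse_hidden_marker <- function(marker) {
  pieces <- strsplit(marker, ";;", fixed = TRUE)[[1]]
  out <- list()
  for (p in pieces) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) next
    out[[kv[[1]]]] <- strsplit(kv[[2]], "|", fixed = TRUE)[[1]]
  }
  out
}

#' Truth table of a pool
#'
#' @param pool List of `synthetic_sample`s.
#' @return Named list: run accession -> truth mapping.
#' @export
truth_table <- function(pool) {
  out <- lapply(pool, `[[`, "truth")
  names(out) <- vapply(pool, `[[`, character(1), "run_accession")
  out
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render SRA-like XML fixtures for a synthetic sample
#'
#' Produces a four-block run XML (context text planted in the study
#' abstract), a BioSample XML whose attributes carry the explicit-mode
#' class values, and an API row for the four API-direct fields — all
#' parseable by the ingestion module, so planted values survive the full
#' pipeline offline.
#'
#' @param sample A `synthetic_sample`.
#' @return `list(run_xml=, biosample_xml=, api_row=)`.
#' @export
render_fixture_xml <- function(sample) {
  acc <- sample$run_accession
  num <- as.integer(sub("^[A-Z]+", "", acc))
  samn <- sprintf("SAMN%08d", as.integer(1e7 + num %% 1e7))
  attrs <- character(0)
  for (cls in names(sample$mode)) {
    if (identical(sample$mode[[cls]], "explicit")) {
      key <- gsub("_", " ", cls)
      val <- paste(sample$truth[[cls]], collapse = "; ")
      attrs <- c(attrs, sprintf(
        '    <Attribute attribute_name="%s">%s</Attribute>',
        xml_escape(key), xml_escape(val)))
    }
  }
  run_xml <- paste0(
    '<EXPERIMENT_PACKAGE_SET>\n<EXPERIMENT_PACKAGE>\n',
    '<STUDY accession="SRP', sprintf("%06d", 1L + num %% 999999L), '">\n',
    '  <DESCRIPTOR>\n',
    '    <STUDY_TITLE>', xml_escape(paste("Synthetic benchmark study",
                                          sample$sample_id)),
    '</STUDY_TITLE>\n',
    '    <STUDY_ABSTRACT>', xml_escape(sample$context_text),
    '</STUDY_ABSTRACT>\n',
    '  </DESCRIPTOR>\n',
    '</STUDY>\n',
    '<SAMPLE accession="', samn, '">\n',
    '  <TITLE>', xml_escape(paste("Sample for", acc)), '</TITLE>\n',
    '  <SAMPLE_LINKS>\n',
    '    <SAMPLE_LINK><XREF_LINK><DB>biosample</DB><ID>', samn,
    '</ID></XREF_LINK></SAMPLE_LINK>\n',
    '  </SAMPLE_LINKS>\n',
    '  <IDENTIFIERS><EXTERNAL_ID namespace="BioSample">', samn,
    '</EXTERNAL_ID></IDENTIFIERS>\n',
    '</SAMPLE>\n',
    '<EXPERIMENT>\n',
    '  <DESIGN><LIBRARY_DESCRIPTOR>',
    '<LIBRARY_STRATEGY>RNA-Seq</LIBRARY_STRATEGY>',
    '</LIBRARY_DESCRIPTOR></DESIGN>\n',
    '</EXPERIMENT>\n',
    '<RUN accession="', acc, '">\n',
    '  <IDENTIFIERS><PRIMARY_ID>', acc, '</PRIMARY_ID></IDENTIFIERS>\n',
    '</RUN>\n',
    '</EXPERIMENT_PACKAGE>\n</EXPERIMENT_PACKAGE_SET>\n')
  biosample_xml <- paste0(
    '<BioSampleSet>\n<BioSample accession="', samn, '">\n',
    '  <Attributes>\n',
    paste(attrs, collapse = "\n"), if (length(attrs)) "\n" else "",
    '  </Attributes>\n',
    '</BioSample>\n</BioSampleSet>\n')
  api_row <- c(
    run_accession = acc,
    study_accession = sprintf("PRJNA%06d", 1L + num %% 999999L),
    instrument_platform = "ILLUMINA",
    number_of_base_pairs = format(1e9 + (num %% 1000L) * 1e6,
                                  scientific = FALSE),
    library_strategy = "RNA-Seq")
  list(run_xml = run_xml, biosample_xml = biosample_xml, api_row = api_row)
}

#' Write a fixture directory for a pool
#'
#' Per sample: `<acc>.run.xml` and `<acc>.biosample.xml`; shared `api.tsv`
#' and `truth.tsv` (run accession, class, values, mode, tier). The layout
#' is what [fixture_fetcher()] reads.
#'
#' @param pool List of `synthetic_sample`s.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(pool, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  api_rows <- list()
  truth_rows <- list()
  for (s in pool) {
    fx <- render_fixture_xml(s)
    writeLines(fx$run_xml, file.path(dir, paste0(s$run_accession,
                                                 ".run.xml")))
    samn <- regmatches(fx$biosample_xml,
                       regexpr("SAMN[0-9]+", fx$biosample_xml))
    writeLines(fx$biosample_xml, file.path(dir, paste0(samn,
                                                       ".biosample.xml")))
    api_rows[[length(api_rows) + 1L]] <- as.data.frame(as.list(fx$api_row),
                                                       stringsAsFactors = FALSE)
    for (cls in names(s$truth)) {
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        run_accession = s$run_accession, class = cls,
        values = paste(s$truth[[cls]], collapse = "|"),
        mode = s$mode[[cls]], tier = s$tier, stringsAsFactors = FALSE)
    }
  }
  utils::write.table(do.call(rbind, api_rows), file.path(dir, "api.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(do.call(rbind, truth_rows), file.path(dir, "truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read the truth table of a fixture directory
#'
#' @param dir Directory written by [write_fixture_dir()].
#' @return Named list: run accession -> truth mapping.
#' @export
read_truth_tsv <- function(dir) {
  tab <- utils::read.delim(file.path(dir, "truth.tsv"),
                           stringsAsFactors = FALSE, quote = "")
  out <- list()
  for (i in seq_len(nrow(tab))) {
    acc <- tab$run_accession[i]
    if (is.null(out[[acc]])) out[[acc]] <- list()
    out[[acc]][[tab$class[i]]] <- strsplit(tab$values[i], "|",
                                           fixed = TRUE)[[1]]
  }
  out
}

#' Token-set Jaccard similarity
#'
#' Default similarity for proximity splitting and leakage diagnostics:
#' intersection over union of the lowercased word sets of two texts.
#' Symmetric, in \[0, 1\]. An embedding-based function with the same
#' signature can be plugged in instead.
#'
#' @param a,b Strings.
#' @return Similarity in \[0, 1\].
#' @export
jaccard_similarity <- function(a, b) {
  sa <- text_word_set(a)
  sb <- text_word_set(b)
  if (!length(sa) && !length(sb)) return(1)
  length(intersect(sa, sb)) / length(union(sa, sb))
}

text_word_set <- function(x) {
  unique(tolower(regmatches(x, gregexpr("[A-Za-z0-9]+", x))[[1]]))
}

#' Split a pool by proximity to a reference set
#'
#' Each sample is scored by its maximum similarity to the reference
#' (train-like) samples, scores are sorted descending with ties broken by
#' sample id, and the pool is cut into ID (closest), MID, and OOD
#' (most distant) partitions of the requested sizes — the three test tiers
#' probing generalization at increasing distance from the training data.
#'
#' @param pool List of `synthetic_sample`s; `length(pool)` must equal
#'   `sum(sizes)`.
#' @param reference List of `synthetic_sample`s (or strings) to score
#'   against.
#' @param sim Similarity function over two strings; default
#'   [jaccard_similarity()].
#' @param sizes Integer triple (ID, MID, OOD); default `c(400, 1200, 400)`.
#' @return `list(ID=, MID=, OOD=)` of samples with their `split` field set;
#'   attribute `scores` holds the per-sample score vector.
#' @export
split_by_proximity <- function(pool, reference, sim = jaccard_similarity,
                               sizes = c(400L, 1200L, 400L)) {
  if (length(pool) != sum(sizes)) {
    stop("pool size (", length(pool), ") must equal sum(sizes) (",
         sum(sizes), ")")
  }
  ref_texts <- vapply(reference, function(r) {
    if (is.character(r)) r else r$context_text
  }, character(1))
  ref_sets <- lapply(ref_texts, text_word_set)
  scores <- vapply(pool, function(s) {
    ws <- text_word_set(s$context_text)
    max(vapply(ref_sets, function(rs) {
      if (!length(ws) && !length(rs)) return(1)
      length(intersect(ws, rs)) / length(union(ws, rs))
    }, numeric(1)))
  }, numeric(1))
  # honor a user-supplied similarity when it is not the default
  if (!identical(sim, jaccard_similarity)) {
    scores <- vapply(pool, function(s) {
      max(vapply(ref_texts, function(rt) sim(s$context_text, rt), numeric(1)))
    }, numeric(1))
  }
  ids <- vapply(pool, `[[`, character(1), "sample_id")
  ord <- order(-scores, ids)
  cut1 <- seq_len(sizes[[1]])
  cut3 <- seq(length(pool) - sizes[[3]] + 1L, length(pool))
  assign_split <- function(idx, name) {
    lapply(pool[ord[idx]], function(s) {
      s$split <- name
      s
    })
  }
  out <- list(ID = assign_split(cut1, "ID"),
              MID = assign_split(setdiff(seq_along(pool),
                                         c(cut1, cut3)), "MID"),
              OOD = assign_split(cut3, "OOD"))
  attr(out, "scores") <- scores[ord]
  out
}

#' Leakage diagnostics across splits
#'
#' Counts cross-split sample pairs whose similarity reaches the threshold
#' (near-duplicates that would let a model score by memorization), and
#' verifies that open-vocabulary truth values are disjoint across splits,
#' reporting any violating values.
#'
#' @param splits Named list of sample lists (e.g. from
#'   [split_by_proximity()]).
#' @param sim Similarity function; default [jaccard_similarity()].
#' @param threshold Similarity threshold in (0, 1].
#' @param open_vocab_classes Classes whose pools must be disjoint.
#' @param count_pairs Set to `FALSE` to skip the quadratic near-duplicate
#'   scan and only run the pool-disjointness check.
#' @return `list(near_duplicates=, pool_violations=)`; `pool_violations` is
#'   a character vector of values seen in more than one split
#'   (`near_duplicates` is `NA` when the pair scan is skipped).
#' @export
leakage_check <- function(splits, sim = jaccard_similarity, threshold = 0.9,
                          open_vocab_classes = c("organ", "biopsy_site",
                                                 "disease", "cell_line",
                                                 "cell_type", "treatment",
                                                 "treatment_time",
                                                 "ethnicity"),
                          count_pairs = TRUE) {
  stopifnot(threshold > 0, threshold <= 1)
  nms <- names(splits)
  sets <- lapply(splits, function(part) {
    lapply(part, function(s) text_word_set(s$context_text))
  })
  count <- if (count_pairs) 0L else NA_integer_
  if (count_pairs) for (i in seq_along(nms)) {
    for (j in seq_along(nms)) {
      if (j <= i) next
      for (a in sets[[i]]) {
        for (b in sets[[j]]) {
          s <- if (!length(a) && !length(b)) 1 else
            length(intersect(a, b)) / length(union(a, b))
          if (s >= threshold) count <- count + 1L
        }
      }
    }
  }
  violations <- character(0)
  for (cls in open_vocab_classes) {
    pools <- lapply(splits, function(part) {
      vals <- unlist(lapply(part, function(s) unlist(s$truth[[cls]])))
      setdiff(unique(vals), "unknown")
    })
    seen <- unlist(pools)
    dup <- unique(seen[duplicated(seen)])
    if (length(dup)) violations <- c(violations, paste0(cls, "=", dup))
  }
  list(near_duplicates = count, pool_violations = violations)
}

# Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
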