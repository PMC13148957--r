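#' Annotation rows
#'
#' A per-run container holding, for each of the 19 classes, an ordered value
#' set plus provenance (`api`, `rule`, `lexicon_propagation`, `llm`, `none`),
#' a status (`validated`, `flagged`, `missing`) and an optional confidence.
#' Ontology identifiers and the losing value of a resolution decision are
#' kept in `ids` / `alt` slots so users can inspect or override them.
#'
#' @param run_accession Run accession string.
#' @param registry A `class_registry` (defines the class slots).
#' @return An empty `annotation_row` with every class `missing`.
#' @export
annotation_row <- function(run_accession, registry = class_registry()) {
  classes <- lapply(registry, function(cls) {
    list(values = character(0), source = "none", status = "missing",
         confidence = NULL, ids = character(0), alt = character(0))
  })
  structure(list(run_accession = run_accession, classes = classes,
                 notes = character(0)),
            class = "annotation_row")
}

set_annotation <- function(row, class_name, values, source, status,
                           confidence = NULL, ids = character(0),
                           alt = character(0)) {
  if (!class_name %in% names(row$classes)) {
    stop("unknown class: ", class_name)
  }
  row$classes[[class_name]] <- list(
    values = unique(values), source = source, status = status,
    confidence = confidence, ids = ids, alt = alt)
  row
}

annotation_of <- function(row, class_name) row$classes[[class_name]]

#' @export
print.annotation_row <- function(x, ...) {
  cat("Annotation row:", x$run_accession, "\n")
  for (cls in names(x$classes)) {
    slot <- x$classes[[cls]]
    if (slot$status == "missing") next
    cat(sprintf("  %-22s %-28s [%s/%s]\n", cls,
                paste(slot$values, collapse = "; "),
                slot$source, slot$status))
  }
  n_missing <- sum(vapply(x$classes, function(s) s$status == "missing",
                          logical(1)))
  if (n_missing) cat("  (", n_missing, "classes missing )\n")
  invisible(x)
}

# Table-driven keyword groups for the library selection heuristic. "." in a
# keyword is separator-elastic: it matches ".", "-", "_", a space, or
# nothing, so "oligo.dT" covers oligo-dT / oligo dT / oligodT.
.library_selection_keywords <- list(
  "polyA" = c("polyA", "poly.A", "oligo.dT", "oligodT", "truseq.mrna",
              "truseq.stranded.mrna", "truseq.standard.mrna", "smarter.mRNA",
              "stranded.mRNA"),
  "inverse rRNA" = c("ribominus", "ribodep", "ribozero", "ribo.zero",
                     "riboerase", "ribogone", "ribocop", "ribo-dep",
                     "ribo-mi", "ribo minus", "depleted ribosom",
                     "remove ribosom", "TruSeq.Stranded.Total", "TruSeq.Total",
                     "SMARTer.Stranded.Total", "SMARTer.Total"),
  "hybrid selection" = c("Hybrid.Selection", "Exon.capture", "Exome.capture",
                         "RNA.Exome", "geoMX"),
  "small RNA" = c("TruSeq.Small", "size.fraction")
)

# keyword -> separator-elastic regex with boundary guards
elastic_pattern <- function(keyword) {
  parts <- strsplit(keyword, "[ .\\-_]+")[[1]]
  parts <- vapply(parts, escape_regex, character(1))
  core <- paste(parts, collapse = "[ ._\\-]?")
  paste0("(?<![A-Za-z0-9])", core, "(?![A-Za-z])")
}

match_keyword_group <- function(text, keywords) {
  for (kw in keywords) {
    if (grepl(elastic_pattern(kw), text, ignore.case = TRUE, perl = TRUE)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Keyword heuristic for library selection
#'
#' Case-insensitive, separator-elastic search of the printed keyword groups,
#' with precedence polyA, inverse rRNA, hybrid selection, small RNA. When no
#' keyword hits, the heuristic abstains (returns `NULL`) rather than
#' defaulting to "other": the "other" fallback belongs to the model prompt,
#' and abstaining here leaves genuinely undecided cases to the model.
#'
#' @param text Context text.
#' @return One of the four labels, or `NULL`.
#' @export
#' @examples
#' heuristic_library_selection("libraries prepared with oligo-dT beads")
heuristic_library_selection <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text)) return(NULL)
  for (label in names(.library_selection_keywords)) {
    if (match_keyword_group(text, .library_selection_keywords[[label]])) {
      return(label)
    }
  }
  NULL
}

.sequencing_source_keywords <- list(
  "single cell" = c("single cell", "single-cell", "scRNA", "10x Chromium",
                    "Smart-seq", "snRNA"),
  "spatial" = c("spatial", "Visium", "in-tissue localization", "GeoMx",
                "slide-seq"),
  "bulk" = c("bulk")
)

#' Keyword heuristic for sequencing source
#'
#' Explicit keyword/synonym search over the three sampling granularities:
#' single cell (scRNA, 10x Chromium, Smart-seq, ...), spatial (Visium,
#' GeoMx, in-tissue localization, ...), and an explicit "bulk". Abstains
#' when nothing is stated.
#'
#' @param text Context text.
#' @return "single cell", "spatial", "bulk", or `NULL`.
#' @export
heuristic_sequencing_source <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text)) return(NULL)
  for (label in names(.sequencing_source_keywords)) {
    if (match_keyword_group(text, .sequencing_source_keywords[[label]])) {
      return(label)
    }
  }
  NULL
}

.metastasis_keywords <- c("metastasis", "metastatic", "metastases",
                          "metastasize")
.blood_keywords <- c("blood", "PBMC", "peripheral blood", "plasma", "serum",
                     "leukocyte", "leukapheresis", "buffy coat")
.cancer_keywords <- c("cancer", "carcinoma", "tumor", "tumour", "melanoma",
                      "leukemia", "leukaemia", "lymphoma", "sarcoma",
                      "glioma", "glioblastoma", "neuroblastoma",
                      "adenocarcinoma", "malignant", "oncology",
                      "oncological", "myeloma")

# Cancer context from keywords plus the disease lexicon's cancer flags.
cancer_context <- function(text, lexicons = NULL) {
  if (match_keyword_group(text, .cancer_keywords)) return(TRUE)
  if (!is.null(lexicons)) {
    for (e in lexicons$disease_map$entries) {
      if (isTRUE(e$cancer) &&
          match_keyword_group(text, c(e$preferred_name, e$synonyms))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Keyword heuristic for biopsy type
#'
#' Three-way rule: "metastasis" only when a cancer context is established
#' and a metastasis keyword is explicitly present; else "blood" when a
#' blood-related keyword is present and no metastasis; else "primary" when
#' a cancer context is established; abstains when no cancer context can be
#' established at the rule stage.
#'
#' @param text Context text.
#' @param is_cancer_hint Optional logical overriding keyword-based cancer
#'   context detection.
#' @return "metastasis", "blood", "primary", or `NULL`.
#' @export
heuristic_biopsy_type <- function(text, is_cancer_hint = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text)) return(NULL)
  cancer <- if (is.null(is_cancer_hint)) cancer_context(text) else
    isTRUE(is_cancer_hint)
  has_met <- match_keyword_group(text, .metastasis_keywords)
  has_blood <- match_keyword_group(text, .blood_keywords)
  if (cancer && has_met) return("metastasis")
  if (has_blood && !has_met) return("blood")
  if (cancer) return("primary")
  NULL
}

#' Cross-source consistency check
#'
#' Candidates for one class collected from several sources are compared
#' after normalization (case-fold, whitespace-collapse). Agreement across
#' sources is preferred: the agreed value is accepted with status
#' `validated`. Disagreeing normalized values are all retained with status
#' `flagged` and an ambiguity note naming the class and both sources, so the
#' downstream model stage sees the conflict. A single-source candidate is
#' accepted if it passes [validate_value()].
#'
#' @param candidates List of `list(value=, source=)` pairs from >= 1 source.
#' @param class The `metadata_class` being filled.
#' @param aliases Alias tables forwarded to [validate_value()].
#' @return `list(values=, status=, notes=)`; `values` empty when every
#'   candidate was rejected.
#' @export
cross_source_check <- function(candidates, class,
                               aliases = .default_value_aliases) {
  stopifnot(length(candidates) >= 1L)
  checked <- lapply(candidates, function(cand) {
    v <- validate_value(class, cand$value, aliases = aliases)
    list(value = cand$value, source = cand$source,
         accepted = v$accepted, norm = v$normalized_value)
  })
  ok <- Filter(function(x) x$accepted, checked)
  if (!length(ok)) {
    return(list(values = character(0), status = "missing",
                notes = character(0)))
  }
  norms <- vapply(ok, function(x) tolower(x$norm), character(1))
  canon <- vapply(ok, `[[`, character(1), "norm")
  if (length(unique(norms)) == 1L) {
    return(list(values = canon[[1]], status = "validated",
                notes = character(0)))
  }
  first_of <- !duplicated(norms)
  note <- paste0(
    class$name, ": ",
    paste(sprintf("source %s says '%s'",
                  vapply(ok[first_of], `[[`, character(1), "source"),
                  canon[first_of]),
          collapse = ", "))
  list(values = unique(canon), status = "flagged", notes = note)
}

#' Default per-class alias tables for tag/attribute extraction
#'
#' Maps each class to the XML tag names and BioSample attribute keys under
#' which submitters commonly store it (keys are matched lowercased and
#' whitespace-collapsed). Configurable: pass an edited copy to
#' [run_rule_stage()].
#'
#' @return Named list: class -> character vector of field keys.
#' @export
default_field_aliases <- function() {
  list(
    sex = c("sex", "gender", "donor sex"),
    age = c("age", "donor age", "age at collection"),
    organ = c("organ", "organism part"),
    biopsy_site = c("biopsy site", "tissue", "organ part", "body site",
                    "source_name", "source name", "isolation source",
                    "biomaterial"),
    disease = c("disease", "diagnosis", "condition", "disease state",
                "health state"),
    cell_line = c("cell line", "cell_line", "cellline"),
    cell_type = c("cell type", "cell_type"),
    ethnicity = c("ethnicity", "race", "ancestry"),
    treatment = c("treatment", "drug", "intervention", "agent"),
    treatment_time = c("treatment time", "timepoint", "time point",
                       "time of treatment"),
    response = c("response", "clinical response", "outcome"),
    library_selection = c("library selection", "library_selection",
                          "libraryselection"),
    sequencing_source = c("sequencing source", "sequencing_source"),
    biopsy_type = c("biopsy type", "biopsy_type"),
    is_cancer = c("is cancer", "is_cancer", "cancer")
  )
}

# API field names accepted for the four API-direct classes.
default_api_aliases <- function() {
  list(
    study_accession = c("study_accession", "study accession", "bioproject"),
    instrument_platform = c("instrument_platform", "platform",
                            "instrument platform"),
    number_of_base_pairs = c("number_of_base_pairs", "bases", "total_bases",
                             "base pairs"),
    library_strategy = c("library_strategy", "library strategy", "strategy")
  )
}

# Collect (value, source) candidates for a class from tagged fields.
collect_candidates <- function(record, keys) {
  groups <- c("sample_fields", "study_fields", "experiment_fields",
              "run_fields", "biosample_attributes", "user_notes")
  out <- list()
  for (g in groups) {
    fields <- record[[g]]
    if (!length(fields)) next
    hit <- names(fields)[tolower(names(fields)) %in% tolower(keys)]
    for (h in hit) {
      out[[length(out) + 1L]] <- list(value = fields[[h]],
                                      source = source_tag_of(g))
    }
  }
  out
}

#' Run the deterministic extraction stage
#'
#' Order of operations: (1) API-direct classes copied from API fields;
#' (2) alias-tagged extraction of class values from XML tags and BioSample
#' attribute keys; (3) gazetteer cell-line matching over the context text;
#' (4) keyword heuristics for library selection, sequencing source and
#' biopsy type where still missing; (5) attribute propagation from a
#' recognized cell line; (6) disease/anatomy normalization to preferred
#' names and identifiers; (7) everything passes type-and-range validation
#' and cross-source consistency; rejected values are dropped (per-class
#' failures degrade to missing, never to an error). Deterministic:
#' identical record, identical row.
#'
#' @param record A merged `run_record`.
#' @param bundle The run's `context_bundle` (used by gazetteer and
#'   heuristics); built from the record when `NULL`.
#' @param lexicons A `lexicon_set`.
#' @param registry A `class_registry`.
#' @param field_aliases Per-class field alias tables.
#' @return An `annotation_row` with statuses and ambiguity notes.
#' @export
run_rule_stage <- function(record, bundle = NULL,
                           lexicons = load_lexicons(),
                           registry = class_registry(),
                           field_aliases = default_field_aliases()) {
  stopifnot(inherits(record, "run_record"))
  if (is.null(bundle)) bundle <- build_context(record)
  row <- annotation_row(record$run_accession, registry)
  text <- bundle_text(bundle)

  # (1) API-direct classes
  api_alias <- default_api_aliases()
  for (cls_name in names(api_direct_classes(registry))) {
    keys <- tolower(api_alias[[cls_name]])
    hit <- names(record$api_fields)[tolower(names(record$api_fields)) %in% keys]
    if (length(hit)) {
      val <- record$api_fields[[hit[[1]]]]
      if (!is_placeholder(val)) {
        row <- set_annotation(row, cls_name, values = squash_ws(val),
                              source = "api", status = "validated")
      }
    }
  }

  # (2) alias-tagged extraction + (7) validation and cross-source checks
  for (cls_name in names(field_aliases)) {
    cls <- registry[[cls_name]]
    if (is.null(cls) || cls$kind == "api_direct") next
    cands <- collect_candidates(record, field_aliases[[cls_name]])
    if (!length(cands)) next
    res <- cross_source_check(cands, cls)
    if (res$status == "missing") next
    row <- set_annotation(row, cls_name, values = res$values,
                          source = "rule", status = res$status)
    row$notes <- c(row$notes, res$notes)
  }

  # (3) gazetteer cell-line matching on free text
  if (annotation_of(row, "cell_line")$status == "missing") {
    hits <- find_phrases(text, lexicons$gazetteer)
    if (nrow(hits)) {
      row <- set_annotation(row, "cell_line", values = hits$canonical[[1]],
                            source = "rule", status = "validated")
    }
  } else {
    # normalize an alias-extracted mention to its canonical name
    slot <- annotation_of(row, "cell_line")
    entry <- lookup_cell_line(slot$values[[1]], lexicons)
    if (!is.null(entry)) {
      row <- set_annotation(row, "cell_line", values = entry$canonical,
                            source = slot$source, status = slot$status)
    }
  }

  # (4) heuristics where still missing
  if (annotation_of(row, "library_selection")$status == "missing") {
    lab <- heuristic_library_selection(text)
    if (!is.null(lab)) {
      row <- set_annotation(row, "library_selection", values = lab,
                            source = "rule", status = "validated")
    }
  }
  if (annotation_of(row, "sequencing_source")$status == "missing") {
    lab <- heuristic_sequencing_source(text)
    if (!is.null(lab)) {
      row <- set_annotation(row, "sequencing_source", values = lab,
                            source = "rule", status = "validated")
    }
  }
  if (annotation_of(row, "biopsy_type")$status == "missing") {
    hint <- cancer_context(text, lexicons)
    lab <- heuristic_biopsy_type(text, is_cancer_hint = hint)
    if (!is.null(lab)) {
      row <- set_annotation(row, "biopsy_type", values = lab,
                            source = "rule", status = "validated")
    }
  }

  # (5) propagation from a recognized cell line
  cl <- annotation_of(row, "cell_line")
  if (cl$status != "missing" && length(cl$values)) {
    entry <- lookup_cell_line(cl$values[[1]], lexicons)
    if (!is.null(entry)) row <- propagate_from_cell_line(entry, row)
  }

  # (6) ontology normalization of disease / organ / biopsy_site
  row <- normalize_row_terms(row, lexicons)
  row
}

# Map disease to the disease term map and organ/biopsy_site to the anatomy
# map, storing preferred names and stable IDs.
normalize_row_terms <- function(row, lexicons) {
  maps <- list(disease = lexicons$disease_map,
               organ = lexicons$anatomy_map,
               biopsy_site = lexicons$anatomy_map)
  for (cls in names(maps)) {
    slot <- annotation_of(row, cls)
    if (slot$status == "missing" || !length(slot$values)) next
    vals <- slot$values
    ids <- slot$ids
    changed <- FALSE
    for (k in seq_along(vals)) {
      hit <- normalize_term(vals[[k]], maps[[cls]])
      if (!is.null(hit)) {
        if (!identical(vals[[k]], hit$preferred_name)) changed <- TRUE
        vals[[k]] <- hit$preferred_name
        ids <- unique(c(ids, hit$term_id))
      }
    }
    if (changed || length(ids) > length(slot$ids)) {
      row <- set_annotation(row, cls, values = vals, source = slot$source,
                            status = slot$status,
                            confidence = slot$confidence, ids = ids,
                            alt = slot$alt)
    }
  }
  row
}
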