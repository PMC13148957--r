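# Shared fixtures, all built in code at test time.

# A context bundle wrapping raw text (bypasses record rendering).
make_bundle <- function(text, notes = character(0)) {
  structure(list(
    paragraphs = data.frame(text = text, source = "sra_xml",
                            stringsAsFactors = FALSE),
    token_count = count_tokens(paste(text, collapse = " ")),
    ambiguity_notes = notes
  ), class = "context_bundle")
}

# A small hand-built run record.
tiny_record <- function(accession = "SRR0000001") {
  rec <- sramend:::empty_run_record()
  rec$run_accession <- accession
  rec$study_fields <- c(study_title = "Melanoma cohort",
                        study_abstract = "RNA profiling of tumor biopsies")
  rec$sample_fields <- c(title = "Patient sample")
  rec
}

# A synthetic sample with every class absent (plant-free context).
sample_all_absent <- function(accession = "SRR8809999") {
  classes <- names(llm_routed_classes(class_registry()))
  truth <- as.list(rep("unknown", length(classes)))
  names(truth) <- classes
  mode <- rep("absent", length(classes))
  names(mode) <- classes
  structure(list(
    sample_id = accession, run_accession = accession,
    context_text = paste(
      "Transcriptome study of human samples.",
      "Libraries were prepared following the standard institutional",
      "protocol and sequenced with paired end chemistry."),
    truth = truth, mode = mode, tier = "ID", split = NA_character_,
    hidden_marker = sramend:::make_hidden_marker(truth)
  ), class = "synthetic_sample")
}

# Shared small lexicon/registry instances (loading is cheap but repeated).
test_lexicons <- load_lexicons()
test_registry <- class_registry()

# Extract final values per class from an annotation row.
row_values <- function(row) {
  lapply(row$classes, function(s) if (length(s$values)) s$values else "unknown")
}
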