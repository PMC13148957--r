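#' Build a paragraph-style context from a run record
#'
#' Renders every stored field as a labeled sentence ("Study title: ...."),
#' grouped by source in a stable order — study, sample, experiment, run,
#' BioSample attributes, API fields, then user notes last. Placeholder
#' values (unknown / missing / not collected / NA / empty) are dropped: they
#' carry no information and would only pad the model context.
#'
#' @param record A merged `run_record`.
#' @param ambiguity_notes Optional character vector of cross-source
#'   disagreement notes (each referencing a class name) to carry along.
#' @return A `context_bundle`: `paragraphs` (data.frame text/source),
#'   `token_count`, `ambiguity_notes`.
#' @export
build_context <- function(record, ambiguity_notes = character(0)) {
  stopifnot(inherits(record, "run_record"))
  groups <- c("study_fields", "sample_fields", "experiment_fields",
              "run_fields", "biosample_attributes", "api_fields",
              "user_notes")
  labels <- c(study_fields = "Study", sample_fields = "Sample",
              experiment_fields = "Experiment", run_fields = "Run",
              biosample_attributes = "BioSample attribute",
              api_fields = "API field", user_notes = "User note")
  texts <- character(0)
  sources <- character(0)
  for (g in groups) {
    fields <- record[[g]]
    if (!length(fields)) next
    keep <- !vapply(fields, is_placeholder, logical(1))
    fields <- fields[keep]
    if (!length(fields)) next
    sent <- sprintf("%s %s: %s.", labels[[g]], names(fields),
                    sub("\\.$", "", unname(fields)))
    texts <- c(texts, sent)
    sources <- c(sources, rep(source_tag_of(g), length(sent)))
  }
  paragraphs <- data.frame(text = texts, source = sources,
                           stringsAsFactors = FALSE)
  new_context_bundle(paragraphs, ambiguity_notes)
}

new_context_bundle <- function(paragraphs, ambiguity_notes = character(0)) {
  structure(list(
    paragraphs = paragraphs,
    token_count = count_tokens(paste(paragraphs$text, collapse = " ")),
    ambiguity_notes = ambiguity_notes
  ), class = "context_bundle")
}

#' @export
print.context_bundle <- function(x, ...) {
  cat("Context bundle:", nrow(x$paragraphs), "sentences,",
      x$token_count, "tokens")
  if (length(x$ambiguity_notes)) {
    cat(",", length(x$ambiguity_notes), "ambiguity notes")
  }
  cat("\n")
  invisible(x)
}

#' Count tokens in a string
#'
#' Budget unit for summarization. The default tokenizer counts maximal runs
#' of non-whitespace characters, which is deterministic, additive over
#' space-joined concatenation, and model-free. A backend-specific tokenizer
#' can be injected wherever a `tokenizer` argument is accepted.
#'
#' @param text A string (NA counts as 0).
#' @return Integer token count.
#' @export
count_tokens <- function(text) {
  if (length(text) == 0L || is.na(text) || !nzchar(trimws(text))) return(0L)
  length(gregexpr("\\S+", text)[[1]])
}

# Accession-shaped identifiers removed during summarization.
.accession_pattern <- "(SRR|SRX|SRS|SRP|PRJ[EDN][A-Z]?|SAMN|SAMEA|GSE|GSM)[0-9]+"

#' Default boilerplate phrases stripped during summarization
#' @return Character vector of phrases (matched case-insensitively).
#' @export
default_boilerplate <- function() {
  c("Keywords:", "GEO Accession", "submission template",
    "Overall design", "please cite", "processed data file")
}

#' Enforce the token budget on a context bundle
#'
#' Contexts at or below the budget pass unchanged. Overlong model contexts
#' hurt extraction, so longer bundles are summarized extractively:
#' accession-shaped identifiers and boilerplate phrases are removed, exact
#' duplicate sentences deleted, and the remaining sentences scored by their
#' rare-term content (sum of inverse within-bundle term frequencies); the
#' highest-scoring sentences are kept greedily, ties broken by earlier
#' position, and re-emitted in document order until the budget is met. A
#' single sentence longer than the whole budget is truncated at a token
#' boundary with a warning. Idempotent: summarizing a summarized bundle is
#' the identity.
#'
#' @param bundle A `context_bundle`.
#' @param budget Token budget (default 2000).
#' @param boilerplate Phrases stripped from sentences before scoring.
#' @return A `context_bundle` with `token_count <= budget`.
#' @export
summarize_context <- function(bundle, budget = 2000L,
                              boilerplate = default_boilerplate()) {
  stopifnot(inherits(bundle, "context_bundle"), budget > 0)
  if (bundle$token_count <= budget) return(bundle)

  para <- bundle$paragraphs
  # split each paragraph into sentences, keep source tags
  sent <- list()
  for (i in seq_len(nrow(para))) {
    pieces <- strsplit(para$text[i], "(?<=[.!?])\\s+", perl = TRUE)[[1]]
    for (p in pieces) {
      sent[[length(sent) + 1L]] <- list(text = p, source = para$source[i])
    }
  }
  clean <- vapply(sent, function(s) {
    t <- gsub(.accession_pattern, "", s$text)
    for (b in boilerplate) {
      t <- gsub(b, "", t, ignore.case = TRUE, fixed = FALSE)
    }
    squash_ws(t)
  }, character(1))
  keep <- nzchar(clean) & !duplicated(clean)
  sent <- sent[keep]
  clean <- clean[keep]
  if (!length(sent)) {
    return(new_context_bundle(
      data.frame(text = character(0), source = character(0),
                 stringsAsFactors = FALSE),
      bundle$ambiguity_notes))
  }

  tok_per <- vapply(clean, count_tokens, integer(1), USE.NAMES = FALSE)
  total <- sum(tok_per)
  if (total > budget) {
    # inverse within-bundle term frequency per sentence
    terms <- lapply(clean, function(t) {
      tolower(regmatches(t, gregexpr("[A-Za-z0-9]+", t))[[1]])
    })
    freq <- table(unlist(terms))
    score <- vapply(terms, function(tt) {
      if (!length(tt)) return(0)
      sum(1 / as.numeric(freq[tt]))
    }, numeric(1))
    ord <- order(-score, seq_along(score))  # score desc, earlier first
    chosen <- logical(length(clean))
    used <- 0L
    for (i in ord) {
      if (used + tok_per[i] <= budget) {
        chosen[i] <- TRUE
        used <- used + tok_per[i]
      }
    }
    if (!any(chosen)) {
      # degenerate: every sentence alone exceeds the budget; truncate the
      # first at a token boundary
      first <- clean[[1]]
      words <- regmatches(first, gregexpr("\\S+", first))[[1]]
      clean <- paste(words[seq_len(budget)], collapse = " ")
      sent <- sent[1]
      warning("single sentence exceeded the token budget; truncated")
      chosen <- TRUE
    }
    sent <- sent[chosen]
    clean <- clean[chosen]
  }
  out <- data.frame(
    text = clean,
    source = vapply(sent, `[[`, character(1), "source"),
    stringsAsFactors = FALSE
  )
  new_context_bundle(out, bundle$ambiguity_notes)
}

# Full text of a bundle, used by heuristics, the gazetteer pass and prompts.
bundle_text <- function(bundle) {
  paste(bundle$paragraphs$text, collapse = " ")
}
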