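#' Load the flat-file lexicons
#'
#' Three TSVs drive normalization: a cell-line registry (canonical name,
#' pipe-separated synonyms, and the attributes a recognized line implies:
#' biopsy_site, cell_type, organ, disease, age, sex, ethnicity), a disease
#' term map (Disease-Ontology-style IDs, preferred names, synonyms, cancer
#' flag) and an anatomy term map (Uberon-style IDs). A compact fixture set
#' ships with the package so nothing is downloaded; full Cellosaurus / DO /
#' Uberon exports in the same schema are drop-in replacements.
#'
#' @param dir Directory holding `cell_lines.tsv`, `diseases.tsv`,
#'   `anatomy.tsv`; defaults to the packaged fixture lexicons.
#' @param stoplist Generic terms never indexed in the gazetteer.
#' @param min_len Minimum phrase length (characters) indexed.
#' @return A `lexicon_set`: cell-line entries, two term maps, and a compiled
#'   gazetteer over cell-line names.
#' @export
load_lexicons <- function(dir = NULL, stoplist = default_stoplist(),
                          min_len = 3L) {
  if (is.null(dir)) {
    dir <- system.file("extdata", "lexicons", package = "sramend")
  }
  if (!dir.exists(dir)) stop("lexicon directory not found: ", dir)
  cells <- read_cell_line_registry(file.path(dir, "cell_lines.tsv"))
  diseases <- read_term_map(file.path(dir, "diseases.tsv"), "disease")
  anatomy <- read_term_map(file.path(dir, "anatomy.tsv"), "anatomy")
  structure(list(
    cell_lines = cells,
    disease_map = diseases,
    anatomy_map = anatomy,
    gazetteer = compile_gazetteer(cells, stoplist = stoplist,
                                  min_len = min_len)
  ), class = "lexicon_set")
}

read_cell_line_registry <- function(path) {
  if (!file.exists(path)) stop("cell line registry not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                           colClasses = "character")
  attrs <- c("biopsy_site", "cell_type", "organ", "disease", "age", "sex",
             "ethnicity")
  entries <- lapply(seq_len(nrow(tab)), function(i) {
    syn <- character(0)
    if (!is.na(tab$synonyms[i]) && nzchar(tab$synonyms[i])) {
      syn <- trimws(strsplit(tab$synonyms[i], "|", fixed = TRUE)[[1]])
    }
    canonical <- squash_ws(tab$canonical[i])
    syn <- setdiff(syn[nzchar(syn)], canonical)
    att <- lapply(attrs, function(a) {
      v <- if (a %in% names(tab)) tab[[a]][i] else NA_character_
      if (is.na(v) || !nzchar(v)) NA_character_ else squash_ws(v)
    })
    names(att) <- attrs
    structure(list(canonical = canonical, synonyms = syn, attributes = att),
              class = "cell_line_entry")
  })
  names(entries) <- vapply(entries, `[[`, character(1), "canonical")
  entries
}

read_term_map <- function(path, ontology_name) {
  if (!file.exists(path)) stop("term map not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                           colClasses = "character")
  if (anyDuplicated(tab$term_id)) stop("duplicate term ids in ", path)
  entries <- lapply(seq_len(nrow(tab)), function(i) {
    syn <- character(0)
    if (!is.na(tab$synonyms[i]) && nzchar(tab$synonyms[i])) {
      syn <- trimws(strsplit(tab$synonyms[i], "|", fixed = TRUE)[[1]])
      syn <- syn[nzchar(syn)]
    }
    list(term_id = tab$term_id[i],
         preferred_name = squash_ws(tab$preferred_name[i]),
         synonyms = syn,
         cancer = if ("cancer" %in% names(tab)) tab$cancer[i] == "1" else NA)
  })
  structure(list(ontology_name = ontology_name, entries = entries),
            class = "term_map")
}

#' Default gazetteer stoplist
#'
#' Common English and generic biology terms purged from the phrase index so
#' that e.g. a cell-line synonym that happens to be "cell" can never fire.
#'
#' @return Character vector of lowercased stop phrases.
#' @export
default_stoplist <- function() {
  c("cell", "cells", "line", "lines", "cell line", "tissue", "human",
    "sample", "samples", "culture", "cancer", "tumor", "tumour", "control",
    "normal", "primary", "blood", "adult", "the", "and", "of", "in")
}

#' Compile a phrase gazetteer from a cell-line registry
#'
#' Canonical names and synonyms are lowercased and indexed for exact
#' case-insensitive lookup at token boundaries; generic terms (stoplist)
#' and phrases shorter than `min_len` are purged. Each indexed phrase maps
#' back to its canonical entry.
#'
#' @param registry Named list of cell-line entries
#'   (see [load_lexicons()]).
#' @param stoplist Phrases never indexed (lowercased).
#' @param min_len Minimum phrase length in characters.
#' @return A `gazetteer` object.
#' @export
compile_gazetteer <- function(registry, stoplist = default_stoplist(),
                              min_len = 3L) {
  if (!length(registry)) stop("cannot compile a gazetteer from an empty registry")
  index <- list()
  for (entry in registry) {
    phrases <- unique(c(entry$canonical, entry$synonyms))
    for (p in phrases) {
      key <- tolower(squash_ws(p))
      if (nchar(key) < min_len) next
      if (key %in% stoplist) next
      if (is.null(index[[key]])) index[[key]] <- entry$canonical
    }
  }
  structure(list(index = index, stoplist = tolower(stoplist),
                 min_len = min_len),
            class = "gazetteer")
}

# Collapse separators between letter and digit runs so that "MCF-7", "MCF 7",
# "MCF.7" and "MCF7" share one key; used by the regex fallback.
elastic_key <- function(x) {
  gsub("[ .\\-]+", "", tolower(x))
}

#' Find gazetteer phrases in text
#'
#' Single pass, exact case-insensitive matching at token boundaries, hits
#' returned in document order with duplicate canonicals removed keeping the
#' first. A lightweight regex fallback additionally catches alphanumeric
#' variants that exact matching misses (hyphens/spaces/dots inserted or
#' removed between letter and digit runs, e.g. "MCF7" for indexed "MCF-7").
#' Overlapping hits resolving to different canonicals keep the longest
#' match, then the earliest.
#'
#' @param text A string.
#' @param gazetteer A compiled [compile_gazetteer()] index.
#' @return Data frame with columns `start`, `end`, `phrase`, `canonical`,
#'   ordered by position; zero rows when nothing matches.
#' @export
find_phrases <- function(text, gazetteer) {
  stopifnot(inherits(gazetteer, "gazetteer"))
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(start = integer(0), end = integer(0),
                      phrase = character(0), canonical = character(0),
                      stringsAsFactors = FALSE))
  }
  hits <- list()
  # exact pass
  for (key in names(gazetteer$index)) {
    pat <- paste0("(?<![A-Za-z0-9])", escape_regex(key), "(?![A-Za-z0-9])")
    m <- gregexpr(pat, text, ignore.case = TRUE, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    lens <- attr(m, "match.length")
    for (j in seq_along(m)) {
      hits[[length(hits) + 1L]] <- list(
        start = as.integer(m[j]), end = as.integer(m[j] + lens[j] - 1L),
        phrase = substr(text, m[j], m[j] + lens[j] - 1L),
        canonical = gazetteer$index[[key]], exact = TRUE)
    }
  }
  # regex fallback on alphanumeric variants: compare separator-collapsed
  # forms of in-text tokens against separator-collapsed index keys
  variant_map <- split(
    unlist(gazetteer$index, use.names = FALSE),
    elastic_key(names(gazetteer$index))
  )
  tok <- gregexpr("[A-Za-z0-9][A-Za-z0-9.\\-]*", text, perl = TRUE)[[1]]
  if (tok[1] != -1L) {
    lens <- attr(tok, "match.length")
    for (j in seq_along(tok)) {
      word <- substr(text, tok[j], tok[j] + lens[j] - 1L)
      ek <- elastic_key(word)
      if (nchar(ek) < gazetteer$min_len) next
      cand <- variant_map[[ek]]
      if (!is.null(cand)) {
        hits[[length(hits) + 1L]] <- list(
          start = as.integer(tok[j]),
          end = as.integer(tok[j] + lens[j] - 1L),
          phrase = word, canonical = cand[[1]], exact = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), end = integer(0),
                      phrase = character(0), canonical = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(hits, function(h) {
    data.frame(start = h$start, end = h$end, phrase = h$phrase,
               canonical = h$canonical, len = h$end - h$start + 1L,
               stringsAsFactors = FALSE)
  }))
  # longest match first, then earliest; drop overlaps, then document order
  df <- df[order(-df$len, df$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    if (i < nrow(df)) {
      for (j in seq(i + 1L, nrow(df))) {
        if (keep[j] && df$start[j] <= df$end[i] && df$end[j] >= df$start[i]) {
          keep[j] <- FALSE
        }
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start), , drop = FALSE]
  df <- df[!duplicated(df$canonical), , drop = FALSE]
  rownames(df) <- NULL
  df[, c("start", "end", "phrase", "canonical")]
}

escape_regex <- function(x) {
  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
}

#' Normalize a free-text term against an ontology term map
#'
#' Case-insensitive match on preferred names first, then synonyms. Returns
#' the preferred name and its stable identifier, or `NULL` when unmatched.
#' `normalize_term(normalize_term(x)$preferred_name)` is a fixed point.
#'
#' @param term Non-empty string.
#' @param term_map A `term_map` from [load_lexicons()].
#' @return `list(preferred_name=, term_id=, cancer=)` or `NULL`.
#' @export
#' @examples
#' lex <- load_lexicons()
#' normalize_term("TB", lex$disease_map)      # tuberculosis
#' normalize_term("mouth", lex$anatomy_map)   # oral cavity
normalize_term <- function(term, term_map) {
  stopifnot(inherits(term_map, "term_map"))
  key <- tolower(squash_ws(term))
  if (!nzchar(key)) stop("term must be non-empty")
  for (e in term_map$entries) {
    if (tolower(e$preferred_name) == key) {
      return(list(preferred_name = e$preferred_name, term_id = e$term_id,
                  cancer = e$cancer))
    }
  }
  for (e in term_map$entries) {
    if (key %in% tolower(e$synonyms)) {
      return(list(preferred_name = e$preferred_name, term_id = e$term_id,
                  cancer = e$cancer))
    }
  }
  NULL
}

# Classes a recognized cell line can fill.
.propagatable_classes <- c("biopsy_site", "cell_type", "organ", "disease",
                           "age", "sex", "ethnicity")

#' Propagate attributes from a recognized cell line
#'
#' Once a run's cell line is resolved to a registry entry, the entry's known
#' attributes (biopsy site, cell type, organ, disease, age, sex, ethnicity)
#' fill the corresponding classes — but only where the row's value is still
#' missing. Existing validated values are never overwritten. Filled values
#' are tagged `source = "lexicon_propagation"`. Idempotent.
#'
#' @param entry A `cell_line_entry`.
#' @param row An `annotation_row` whose `cell_line` resolves to
#'   `entry$canonical`.
#' @return The updated `annotation_row`.
#' @export
propagate_from_cell_line <- function(entry, row) {
  stopifnot(inherits(entry, "cell_line_entry"), inherits(row, "annotation_row"))
  for (cls in .propagatable_classes) {
    att <- entry$attributes[[cls]]
    if (is.null(att) || is.na(att)) next
    slot <- row$classes[[cls]]
    if (is.null(slot) || slot$status == "missing") {
      row <- set_annotation(row, cls, values = att,
                            source = "lexicon_propagation",
                            status = "validated")
    }
  }
  row
}

# Resolve a raw cell-line mention to a registry entry (exact or elastic).
lookup_cell_line <- function(raw, lexicons) {
  key <- tolower(squash_ws(raw))
  idx <- lexicons$gazetteer$index
  if (!is.null(idx[[key]])) return(lexicons$cell_lines[[idx[[key]]]])
  ek <- elastic_key(raw)
  for (k in names(idx)) {
    if (elastic_key(k) == ek) return(lexicons$cell_lines[[idx[[k]]]])
  }
  NULL
}
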