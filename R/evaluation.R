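#' Hybrid correctness check for one prediction
#'
#' Closed classes (discrete, boolean) require case-insensitive exact label
#' equality on the full value set. Open-vocabulary classes are scored
#' context-tolerantly: the prediction counts as correct when any predicted
#' value matches any reference value, where a match is normalized string
#' equality, a shared ontology/lexicon identifier, or a listed synonym pair
#' (so organ "mouth" matches reference "oral cavity"). A strict full-set
#' mode for open vocabulary is available via `multi = "all"`.
#'
#' @param pred,ref Non-empty character vectors of values.
#' @param class The `metadata_class` being scored.
#' @param lexicons A `lexicon_set` providing the synonym relations.
#' @param multi `"any"` (default) or `"all"`: whether one overlapping value
#'   suffices for open-vocabulary classes or every predicted value must
#'   match.
#' @return Logical flag.
#' @export
#' @examples
#' lex <- load_lexicons()
#' reg <- class_registry()
#' hybrid_match("mouth", "oral cavity", reg$organ, lex)  # TRUE
hybrid_match <- function(pred, ref, class, lexicons = load_lexicons(),
                         multi = c("any", "all")) {
  multi <- match.arg(multi)
  stopifnot(length(pred) >= 1L, length(ref) >= 1L,
            inherits(class, "metadata_class"))
  if (class$kind %in% c("discrete", "boolean")) {
    return(setequal(tolower(trimws(pred)), tolower(trimws(ref))))
  }
  pair_ok <- function(p, r) values_equivalent(p, r, class, lexicons)
  if (multi == "any") {
    for (p in pred) for (r in ref) if (pair_ok(p, r)) return(TRUE)
    return(FALSE)
  }
  all(vapply(pred, function(p) {
    any(vapply(ref, function(r) pair_ok(p, r), logical(1)))
  }, logical(1)))
}

# Normalized equality, shared lexicon ID, or synonym-pair equivalence.
values_equivalent <- function(p, r, class, lexicons) {
  np <- tolower(squash_ws(p))
  nr <- tolower(squash_ws(r))
  if (np == nr) return(TRUE)
  if (np == "unknown" || nr == "unknown") return(FALSE)
  map <- switch(class$name,
    disease = lexicons$disease_map,
    organ = , biopsy_site = lexicons$anatomy_map,
    NULL)
  if (!is.null(map)) {
    hp <- normalize_term(p, map)
    hr <- normalize_term(r, map)
    if (!is.null(hp) && !is.null(hr) &&
        identical(hp$term_id, hr$term_id)) {
      return(TRUE)
    }
  }
  if (class$name == "cell_line") {
    ep <- lookup_cell_line(p, lexicons)
    er <- lookup_cell_line(r, lexicons)
    if (!is.null(ep) && !is.null(er) &&
        identical(ep$canonical, er$canonical)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Per-class accuracy under hybrid matching
#'
#' Fraction of aligned prediction/reference pairs that
#' [hybrid_match()] accepts. With `exclude_unknown_refs` (the convention
#' for reporting on annotated data), pairs whose reference is "unknown" or
#' "not applicable" are dropped first; when nothing remains the result is
#' undefined and returned as `NA` with attribute `undefined = TRUE`.
#'
#' @param preds,refs Lists of character vectors, aligned.
#' @param class The `metadata_class`.
#' @param lexicons A `lexicon_set`.
#' @param exclude_unknown_refs Drop reference-unknown pairs first.
#' @return Accuracy in \[0, 1\], or undefined-flagged `NA`.
#' @export
class_accuracy <- function(preds, refs, class, lexicons = load_lexicons(),
                           exclude_unknown_refs = TRUE) {
  stopifnot(length(preds) == length(refs))
  if (exclude_unknown_refs) {
    keep <- !vapply(refs, function(r) {
      all(tolower(trimws(r)) %in% c("unknown", "not applicable"))
    }, logical(1))
    preds <- preds[keep]
    refs <- refs[keep]
  }
  if (!length(refs)) {
    return(structure(NA_real_, undefined = TRUE))
  }
  hits <- mapply(function(p, r) hybrid_match(p, r, class, lexicons),
                 preds, refs)
  mean(hits)
}

#' Trivial baselines for a class
#'
#' `majority_accuracy`: accuracy of always predicting the most frequent
#' reference label. `unknown_accuracy`: accuracy of always answering
#' "unknown". Reported alongside model accuracy so majority-class bias and
#' over-abstention are visible.
#'
#' @param refs List (or vector) of reference values; multi-valued refs are
#'   keyed by their rendered form.
#' @return `list(majority_accuracy=, unknown_accuracy=)`.
#' @export
baselines <- function(refs) {
  stopifnot(length(refs) > 0L)
  keys <- vapply(refs, function(r) {
    tolower(paste(trimws(r), collapse = ", "))
  }, character(1))
  tab <- table(keys)
  list(majority_accuracy = max(tab) / length(keys),
       unknown_accuracy = mean(keys == "unknown"))
}

#' Abstention versus substitution error taxonomy
#'
#' Partitions the errors (pairs failing [hybrid_match()]) into abstentions
#' — the model answered "unknown" although the reference is known — and
#' substitutions — a wrong non-unknown value. Substitutions are tallied as
#' `class=value` frequency patterns. The two fractions sum to 1 over
#' errors; with no errors the report is empty.
#'
#' @param preds,refs Aligned lists of character vectors.
#' @param class The `metadata_class`.
#' @param lexicons A `lexicon_set`.
#' @return `list(n_errors=, abstention_fraction=, substitution_fraction=,
#'   substitution_patterns=)` (`NULL` fractions when no errors).
#' @export
error_taxonomy <- function(preds, refs, class, lexicons = load_lexicons()) {
  stopifnot(length(preds) == length(refs))
  wrong <- mapply(function(p, r) !hybrid_match(p, r, class, lexicons),
                  preds, refs)
  if (!any(wrong)) {
    return(list(n_errors = 0L, abstention_fraction = NULL,
                substitution_fraction = NULL,
                substitution_patterns = table(character(0))))
  }
  wp <- preds[wrong]
  abst <- vapply(wp, function(p) {
    all(tolower(trimws(p)) == "unknown")
  }, logical(1))
  subs <- wp[!abst]
  patterns <- vapply(subs, function(p) {
    paste0(class$name, "=", paste(p, collapse = "; "))
  }, character(1))
  list(
    n_errors = sum(wrong),
    abstention_fraction = mean(abst),
    substitution_fraction = mean(!abst),
    substitution_patterns = sort(table(patterns), decreasing = TRUE)
  )
}

#' Evaluation report over several classes
#'
#' Per class: n scored pairs, hybrid accuracy, the two trivial baselines,
#' abstention share of errors, and the top substitution pattern. Written as
#' TSV by `write_evaluation_tsv()`.
#'
#' @param predictions Named list: accession -> named list class -> values.
#' @param truths Named list with the same shape (e.g. [truth_table()]).
#' @param classes Class names to score; default: all shared classes.
#' @param registry A `class_registry`.
#' @param lexicons A `lexicon_set`.
#' @param exclude_unknown_refs Forwarded to [class_accuracy()].
#' @return A data.frame, one row per class.
#' @export
evaluation_report <- function(predictions, truths, classes = NULL,
                              registry = class_registry(),
                              lexicons = load_lexicons(),
                              exclude_unknown_refs = TRUE) {
  accs <- intersect(names(predictions), names(truths))
  if (!length(accs)) stop("no shared accessions between predictions and truth")
  if (is.null(classes)) {
    classes <- intersect(names(registry),
                         unique(unlist(lapply(truths, names))))
  }
  rows <- lapply(classes, function(cn) {
    cls <- registry[[cn]]
    preds <- lapply(accs, function(a) {
      v <- predictions[[a]][[cn]]
      if (is.null(v) || !length(v)) "unknown" else v
    })
    refs <- lapply(accs, function(a) {
      v <- truths[[a]][[cn]]
      if (is.null(v) || !length(v)) "unknown" else v
    })
    acc <- class_accuracy(preds, refs, cls, lexicons,
                          exclude_unknown_refs = exclude_unknown_refs)
    base <- baselines(refs)
    tax <- error_taxonomy(preds, refs, cls, lexicons)
    top_sub <- if (length(tax$substitution_patterns)) {
      names(tax$substitution_patterns)[[1]]
    } else {
      ""
    }
    data.frame(
      class = cn,
      n = length(refs),
      accuracy = as.numeric(acc),
      majority_baseline = base$majority_accuracy,
      unknown_baseline = base$unknown_accuracy,
      abstention_fraction = if (is.null(tax$abstention_fraction)) NA_real_
        else tax$abstention_fraction,
      top_substitution = top_sub,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' @rdname evaluation_report
#' @param report A data.frame from `evaluation_report()`.
#' @param path Output TSV path.
#' @export
write_evaluation_tsv <- function(report, path) {
  utils::write.table(report, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
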