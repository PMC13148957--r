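#' Merge rule-stage and model values for one run
#'
#' Two policies:
#' * `"locked"` (default): values extracted and validated by the rule stage
#'   are considered true and locked; model predictions fill only classes
#'   that are missing or were flagged by the cross-source check.
#' * `"per_class_preference"`: for each class, the source named by its
#'   registry `resolution_preference` wins when both are present — the rule
#'   value for library selection and treatment, the model value otherwise.
#'
#' Either way the losing value is retained in the `alt` provenance slot so
#' it can be inspected or overridden downstream. Model answers of
#' "unknown" never displace a real value.
#'
#' @param curated `annotation_row` from [run_rule_stage()].
#' @param predictions Named list of `prediction`s for the same run.
#' @param policy `"locked"` or `"per_class_preference"`.
#' @param registry A `class_registry`.
#' @return The resolved `annotation_row`.
#' @export
resolve_row <- function(curated, predictions,
                        policy = c("locked", "per_class_preference"),
                        registry = class_registry()) {
  policy <- match.arg(policy)
  stopifnot(inherits(curated, "annotation_row"))
  row <- curated
  for (p in predictions) {
    cls_name <- p$class_name
    cls <- registry[[cls_name]]
    if (is.null(cls) || cls$kind == "api_direct") next
    slot <- annotation_of(row, cls_name)
    pred_known <- !identical(p$values, "unknown") && length(p$values) > 0L
    if (slot$status == "missing" || slot$status == "flagged") {
      if (pred_known) {
        row <- set_annotation(row, cls_name, values = p$values,
                              source = "llm", status = "validated",
                              confidence = p$confidence,
                              alt = if (slot$status == "flagged")
                                slot$values else character(0))
      }
      next
    }
    # rule value present and validated
    if (policy == "per_class_preference" && pred_known &&
        cls$resolution_preference == "llm" &&
        !setequal(tolower(slot$values), tolower(p$values))) {
      row <- set_annotation(row, cls_name, values = p$values,
                            source = "llm", status = "validated",
                            confidence = p$confidence, ids = character(0),
                            alt = slot$values)
    } else if (pred_known &&
               !setequal(tolower(slot$values), tolower(p$values))) {
      # locked (or rule-preferred class): keep rule value, stash the model's
      slot$alt <- unique(c(slot$alt, p$values))
      row$classes[[cls_name]] <- slot
    }
  }
  row
}

#' Post-hoc propagation and normalization
#'
#' After resolution: a cell line introduced by the model is normalized to
#' its canonical registry name and, where resolvable, its known attributes
#' fill still-missing dependent classes; then disease, organ and biopsy
#' site values are normalized to preferred ontology names with stable
#' identifiers. Identity when there is nothing new to do.
#'
#' @param row A resolved `annotation_row`.
#' @param lexicons A `lexicon_set`.
#' @return The updated `annotation_row`.
#' @export
post_propagate <- function(row, lexicons = load_lexicons()) {
  stopifnot(inherits(row, "annotation_row"))
  cl <- annotation_of(row, "cell_line")
  if (cl$status != "missing" && length(cl$values)) {
    entry <- lookup_cell_line(cl$values[[1]], lexicons)
    if (!is.null(entry)) {
      if (!identical(cl$values, entry$canonical)) {
        row <- set_annotation(row, "cell_line", values = entry$canonical,
                              source = cl$source, status = cl$status,
                              confidence = cl$confidence,
                              alt = cl$alt)
      }
      row <- propagate_from_cell_line(entry, row)
    }
  }
  normalize_row_terms(row, lexicons)
}

#' Export annotation rows to tabular files
#'
#' One row per run; one column per class plus per-class `_source`,
#' `_status`, `_ppl`, `_id` and `_alt` provenance columns. CSV, TSV and
#' JSON are always available; Parquet and Feather require the optional
#' `arrow` capability; XLSX has no writer capability in this build. A
#' requested format whose capability is absent raises a clear error listing
#' the available formats. All formats reload to identical logical content.
#'
#' @param rows List of `annotation_row`s.
#' @param formats Character vector among csv, tsv, json, parquet, feather,
#'   xlsx.
#' @param path_prefix Output path prefix; `<prefix>.<ext>` is written.
#' @return Named character vector of written paths.
#' @export
export_table <- function(rows, formats = c("tsv"), path_prefix) {
  stopifnot(length(rows) > 0L)
  have_arrow <- requireNamespace("arrow", quietly = TRUE)
  available <- c("csv", "tsv", "json",
                 if (have_arrow) c("parquet", "feather"))
  bad <- setdiff(formats, available)
  if (length(bad)) {
    stop("unsupported format(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(available, collapse = ", "))
  }
  df <- rows_to_data_frame(rows)
  paths <- character(0)
  for (fmt in formats) {
    path <- paste0(path_prefix, ".", fmt)
    switch(fmt,
      csv = utils::write.csv(df, path, row.names = FALSE, na = ""),
      tsv = utils::write.table(df, path, sep = "\t", row.names = FALSE,
                               quote = FALSE, na = ""),
      json = jsonlite::write_json(df, path, dataframe = "rows",
                                  auto_unbox = TRUE, digits = NA, na = "null"),
      parquet = arrow::write_parquet(df, path),
      feather = arrow::write_feather(df, path)
    )
    paths[[fmt]] <- path
  }
  paths
}

#' Flatten annotation rows into a data frame
#'
#' @param rows List of `annotation_row`s.
#' @param registry A `class_registry`.
#' @return A data.frame, one row per run.
#' @export
rows_to_data_frame <- function(rows, registry = class_registry()) {
  cls_names <- names(registry)
  one <- function(row) {
    out <- list(run_accession = row$run_accession)
    for (cn in cls_names) {
      slot <- row$classes[[cn]]
      out[[cn]] <- if (length(slot$values)) {
        paste(slot$values, collapse = "; ")
      } else {
        "unknown"
      }
      out[[paste0(cn, "_source")]] <- slot$source
      out[[paste0(cn, "_status")]] <- slot$status
      out[[paste0(cn, "_ppl")]] <- if (!is.null(slot$confidence)) {
        as.numeric(slot$confidence$ppl)
      } else {
        NA_real_
      }
      out[[paste0(cn, "_id")]] <- paste(slot$ids, collapse = "; ")
      out[[paste0(cn, "_alt")]] <- paste(slot$alt, collapse = "; ")
    }
    as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
  }
  df <- do.call(rbind, lapply(rows, one))
  rownames(df) <- NULL
  df
}

#' Reload an exported table
#'
#' @param path File written by [export_table()].
#' @return A data.frame with the same logical content.
#' @export
read_exported_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA),
    tsv = utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                            check.names = FALSE),
    json = as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                         stringsAsFactors = FALSE, check.names = FALSE),
    parquet = as.data.frame(arrow::read_parquet(path)),
    feather = as.data.frame(arrow::read_feather(path)),
    stop("unknown table format: ", ext)
  )
  # empty strings in character columns are absent values
  for (j in seq_along(df)) {
    if (is.character(df[[j]])) df[[j]][is.na(df[[j]])] <- ""
    if (is.logical(df[[j]]) && all(is.na(df[[j]]))) {
      df[[j]] <- rep("", nrow(df))
    }
  }
  df
}

#' Plain-text summary of an annotated table
#'
#' Per-class fill rate (fraction of runs with a non-missing, non-unknown
#' value), value frequency tables, and quantiles of the per-class
#' perplexity confidence. The tabular portion of quick quality checks;
#' no graphics.
#'
#' @param rows List of `annotation_row`s.
#' @param registry A `class_registry`.
#' @return A `table_summary`: `fill_rates` (named numeric),
#'   `value_frequencies` (named list of tables), `ppl_quantiles` (numeric
#'   vector, NULL when no confidences present).
#' @export
summarize_table <- function(rows, registry = class_registry()) {
  stopifnot(length(rows) > 0L)
  cls_names <- names(registry)
  fill <- numeric(0)
  freqs <- list()
  ppls <- numeric(0)
  for (cn in cls_names) {
    vals <- vapply(rows, function(r) {
      slot <- r$classes[[cn]]
      if (!length(slot$values)) "unknown" else
        paste(slot$values, collapse = "; ")
    }, character(1))
    known <- !vapply(vals, is_placeholder, logical(1))
    fill[[cn]] <- mean(known)
    if (any(known)) freqs[[cn]] <- sort(table(vals[known]), decreasing = TRUE)
    p <- unlist(lapply(rows, function(r) {
      conf <- r$classes[[cn]]$confidence
      if (!is.null(conf) && !is.na(conf$ppl)) conf$ppl else NULL
    }))
    ppls <- c(ppls, p)
  }
  structure(list(
    fill_rates = fill,
    value_frequencies = freqs,
    ppl_quantiles = if (length(ppls)) {
      stats::quantile(ppls, c(0, 0.25, 0.5, 0.75, 1), names = TRUE)
    } else {
      NULL
    },
    n_runs = length(rows)
  ), class = "table_summary")
}

#' @export
print.table_summary <- function(x, ...) {
  cat("Annotated table summary:", x$n_runs, "runs\n")
  cat("Per-class fill rate:\n")
  for (cn in names(x$fill_rates)) {
    cat(sprintf("  %-22s %.3f\n", cn, x$fill_rates[[cn]]))
  }
  if (!is.null(x$ppl_quantiles)) {
    cat("Perplexity quantiles:\n")
    print(round(x$ppl_quantiles, 3))
  }
  invisible(x)
}

#' Write a table summary as TSV
#'
#' @param summary A `table_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(summary, path) {
  df <- data.frame(class = names(summary$fill_rates),
                   fill_rate = unname(summary$fill_rates),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
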