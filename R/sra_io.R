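#' Parse an SRA run XML document into a partial run record
#'
#' An SRA run-level record is structured into four blocks — STUDY, SAMPLE,
#' EXPERIMENT, RUN — describing the project, the sample, the experimental
#' setup and the sequencing run. Both a single-run document and an
#' E-utilities package-of-runs document are accepted; with a package, the
#' first run element is parsed (use [parse_run_xml_set()] for all of them).
#' Leaf text nodes inside each block are flattened into label/text pairs,
#' labels lowercased, text whitespace-normalized. Absent blocks yield empty
#' field groups. SAMPLE_ATTRIBUTES-style TAG/VALUE pairs are folded into
#' `tag: value` entries.
#'
#' @param xml_text Raw XML as a string.
#' @param accession Optional accession used to name parse errors.
#' @return A `run_record` with `study_fields`, `sample_fields`,
#'   `experiment_fields`, `run_fields` populated and the other groups empty.
#' @export
parse_run_xml <- function(xml_text, accession = NULL) {
  doc <- tryCatch(
    xml2::read_xml(xml_text),
    error = function(e) {
      stop("malformed SRA XML",
           if (!is.null(accession)) paste0(" for ", accession) else "",
           ": ", conditionMessage(e), call. = FALSE)
    }
  )
  blocks <- c(STUDY = "study_fields", SAMPLE = "sample_fields",
              EXPERIMENT = "experiment_fields", RUN = "run_fields")
  rec <- empty_run_record()
  for (block in names(blocks)) {
    node <- xml2::xml_find_first(doc, paste0(".//", block))
    rec[[blocks[[block]]]] <- if (inherits(node, "xml_node")) {
      flatten_block(node)
    } else {
      character(0)
    }
  }
  run_node <- xml2::xml_find_first(doc, ".//RUN")
  acc <- NA_character_
  if (inherits(run_node, "xml_node")) {
    acc <- xml2::xml_attr(run_node, "accession")
    if (is.na(acc)) {
      pid <- xml2::xml_find_first(run_node, ".//PRIMARY_ID")
      if (inherits(pid, "xml_node")) acc <- xml2::xml_text(pid)
    }
  }
  if (is.na(acc) && !is.null(accession)) acc <- accession
  rec$run_accession <- if (is.na(acc)) "" else squash_ws(acc)
  class(rec) <- "run_record"
  rec
}

#' @rdname parse_run_xml
#' @return `parse_run_xml_set()`: a list of `run_record`s, one per run
#'   element in a package document.
#' @export
parse_run_xml_set <- function(xml_text) {
  doc <- tryCatch(xml2::read_xml(xml_text), error = function(e) {
    stop("malformed SRA XML: ", conditionMessage(e), call. = FALSE)
  })
  pkgs <- xml2::xml_find_all(doc, ".//EXPERIMENT_PACKAGE")
  if (!length(pkgs)) return(list(parse_run_xml(xml_text)))
  lapply(pkgs, function(p) parse_run_xml(as.character(p)))
}

# Flatten every leaf element under a block into label -> text. Attribute
# TAG/VALUE pairs become one entry keyed by the lowercased tag.
flatten_block <- function(node) {
  out <- character(0)
  tag_nodes <- xml2::xml_find_all(node, ".//TAG")
  for (tn in tag_nodes) {
    vn <- xml2::xml_find_first(tn, "following-sibling::VALUE")
    if (inherits(vn, "xml_node")) {
      key <- tolower(squash_ws(xml2::xml_text(tn)))
      val <- squash_ws(xml2::xml_text(vn))
      if (nzchar(key) && nzchar(val) && !key %in% names(out)) {
        out[[key]] <- val
      }
    }
  }
  leaves <- xml2::xml_find_all(node, ".//*[not(*)]")
  for (lf in leaves) {
    nm <- xml2::xml_name(lf)
    if (nm %in% c("TAG", "VALUE")) next
    key <- tolower(nm)
    val <- squash_ws(xml2::xml_text(lf))
    if (!nzchar(val)) next
    if (key %in% names(out)) next  # first occurrence wins
    out[[key]] <- val
  }
  out
}

empty_run_record <- function() {
  structure(
    list(
      run_accession = "",
      study_fields = character(0),
      sample_fields = character(0),
      experiment_fields = character(0),
      run_fields = character(0),
      biosample_accession = NA_character_,
      biosample_attributes = character(0),
      api_fields = character(0),
      user_notes = character(0)
    ),
    class = "run_record"
  )
}

#' @export
print.run_record <- function(x, ...) {
  cat("SRA run record:", x$run_accession, "\n")
  for (grp in c("study_fields", "sample_fields", "experiment_fields",
                "run_fields", "biosample_attributes", "api_fields",
                "user_notes")) {
    if (length(x[[grp]])) {
      cat(" ", grp, sprintf("(%d; source=%s)", length(x[[grp]]),
                            source_tag_of(grp)), "\n")
    }
  }
  if (!is.na(x$biosample_accession)) {
    cat("  biosample:", x$biosample_accession, "\n")
  }
  invisible(x)
}

# Provenance tag carried by each field group.
source_tag_of <- function(group) {
  switch(group,
    study_fields = , sample_fields = , experiment_fields = ,
    run_fields = "sra_xml",
    biosample_attributes = "biosample",
    api_fields = "api",
    user_notes = "user",
    stop("unknown field group: ", group)
  )
}

#' Resolve the BioSample accession for a run
#'
#' Looks first at cross-reference elements (XREF_LINK, EXTERNAL_ID); when
#' those are absent, falls back to a regular-expression search for a
#' SAMN-plus-digits token anywhere in the raw XML text.
#'
#' @param record A `run_record` (currently unused beyond its contract; the
#'   accession lives in the XML).
#' @param xml_text The raw run XML string.
#' @return The accession string, or `NA_character_` when none is found.
#' @export
resolve_biosample_accession <- function(record, xml_text) {
  doc <- tryCatch(xml2::read_xml(xml_text), error = function(e) NULL)
  if (!is.null(doc)) {
    for (xp in c(".//EXTERNAL_ID[@namespace='BioSample']", ".//EXTERNAL_ID",
                 ".//XREF_LINK/ID", ".//XREF_LINK//ID")) {
      nodes <- xml2::xml_find_all(doc, xp)
      for (n in nodes) {
        txt <- squash_ws(xml2::xml_text(n))
        if (grepl("^SAMN[0-9]+$", txt)) return(txt)
      }
    }
  }
  m <- regmatches(xml_text, regexpr("SAMN[0-9]+", xml_text))
  if (length(m) && nzchar(m)) m else NA_character_
}

#' Parse a BioSample XML document into an attribute mapping
#'
#' Each `Attribute` element becomes one entry keyed by its attribute name
#' (lowercased, whitespace-collapsed), value whitespace-normalized.
#' Duplicate keys keep the first occurrence; collisions are recorded in the
#' `collisions` attribute of the result and reported as a message.
#'
#' @param xml_text Raw BioSample XML.
#' @return Named character vector of attributes (possibly empty).
#' @export
parse_biosample_xml <- function(xml_text) {
  doc <- tryCatch(xml2::read_xml(xml_text), error = function(e) {
    stop("malformed BioSample XML: ", conditionMessage(e), call. = FALSE)
  })
  nodes <- xml2::xml_find_all(doc, ".//Attribute")
  out <- character(0)
  collisions <- character(0)
  for (n in nodes) {
    key <- xml2::xml_attr(n, "attribute_name")
    if (is.na(key)) key <- xml2::xml_attr(n, "name")
    if (is.na(key)) next
    key <- tolower(squash_ws(key))
    val <- squash_ws(xml2::xml_text(n))
    if (!nzchar(key)) next
    if (key %in% names(out)) {
      collisions <- c(collisions, key)
      next
    }
    out[[key]] <- val
  }
  if (length(collisions)) {
    message("BioSample attribute collisions (first kept): ",
            paste(unique(collisions), collapse = ", "))
    attr(out, "collisions") <- unique(collisions)
  }
  out
}

#' Merge all metadata sources into one run record
#'
#' Attaches BioSample attributes, API fields and optional user-supplement
#' notes to a parsed run record. Sources coexist under their own provenance
#' tags; nothing overwrites anything — conflicting values are reconciled
#' later by the cross-source consistency check of the rule stage.
#'
#' @param run_part A `run_record` from [parse_run_xml()].
#' @param biosample Named character vector of BioSample attributes.
#' @param api_row Named character vector (or 1-row data.frame) of API fields.
#' @param user_row Optional named character vector of user-supplement values.
#' @param biosample_accession Optional resolved accession to record.
#' @return The completed `run_record`.
#' @export
merge_sources <- function(run_part, biosample = character(0),
                          api_row = character(0), user_row = NULL,
                          biosample_accession = NA_character_) {
  stopifnot(inherits(run_part, "run_record"))
  if (!nzchar(run_part$run_accession)) {
    stop("run record must carry a run accession before merging")
  }
  as_chr_map <- function(x) {
    if (is.null(x)) return(character(0))
    if (is.data.frame(x)) x <- unlist(x[1, , drop = TRUE])
    out <- vapply(x, as.character, character(1))
    names(out) <- names(x)
    out[!is.na(out) & nzchar(out)]
  }
  rec <- run_part
  rec$biosample_attributes <- as_chr_map(biosample)
  rec$api_fields <- as_chr_map(api_row)
  rec$user_notes <- as_chr_map(user_row)
  if (!is.na(biosample_accession)) {
    rec$biosample_accession <- biosample_accession
  }
  rec
}

# Total number of stored values across all groups; merge_sources is lossless
# under this count.
n_stored_values <- function(record) {
  sum(vapply(c("study_fields", "sample_fields", "experiment_fields",
               "run_fields", "biosample_attributes", "api_fields",
               "user_notes"),
             function(g) length(record[[g]]), integer(1)))
}

#' Read a user-supplied metadata supplement
#'
#' A TSV/CSV with a required run accession column (`run_accession`, or
#' `run`/`accession`) and any number of extra text columns; rows are keyed
#' by accession. Duplicate accessions have their column values concatenated
#' with `" | "` and a warning is issued.
#'
#' @param table_path Path to the tabular file; delimiter inferred from the
#'   extension (`.csv` vs anything else = TSV).
#' @return Named list: accession -> named character vector of notes.
#' @export
read_user_supplement <- function(table_path) {
  if (!file.exists(table_path)) stop("supplement file not found: ", table_path)
  sep <- if (grepl("\\.csv$", table_path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(table_path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           check.names = FALSE, colClasses = "character")
  acc_col <- intersect(c("run_accession", "run", "accession"), names(tab))
  if (!length(acc_col)) {
    stop("user supplement must contain a run accession column ",
         "(expected 'run_accession')")
  }
  acc_col <- acc_col[[1]]
  note_cols <- setdiff(names(tab), acc_col)
  out <- list()
  dups <- character(0)
  for (i in seq_len(nrow(tab))) {
    acc <- tab[[acc_col]][i]
    row <- vapply(note_cols, function(cn) tab[[cn]][i], character(1))
    row <- row[!is.na(row) & nzchar(row)]
    if (acc %in% names(out)) {
      dups <- c(dups, acc)
      for (cn in names(row)) {
        out[[acc]][[cn]] <- if (cn %in% names(out[[acc]])) {
          paste(out[[acc]][[cn]], row[[cn]], sep = " | ")
        } else {
          row[[cn]]
        }
      }
    } else {
      out[[acc]] <- row
    }
  }
  if (length(dups)) {
    warning("duplicate accession rows concatenated: ",
            paste(unique(dups), collapse = ", "))
  }
  out
}

#' Offline fixture fetcher
#'
#' The fetcher contract has three methods: `fetch_run_xml(accession)`,
#' `fetch_biosample_xml(accession)` and `fetch_api_row(accession)`. The
#' fixture implementation resolves everything from a local directory laid
#' out as written by [write_fixture_dir()]: `<acc>.run.xml`,
#' `<acc>.biosample.xml` and a shared `api.tsv` keyed by run accession. No
#' network is touched; this is the mode exercised by the whole test suite.
#'
#' @param dir Fixture directory.
#' @return A list of the three functions, class `fixture_fetcher`.
#' @export
fixture_fetcher <- function(dir) {
  if (!dir.exists(dir)) stop("fixture directory not found: ", dir)
  api_path <- file.path(dir, "api.tsv")
  api_tab <- if (file.exists(api_path)) {
    utils::read.delim(api_path, stringsAsFactors = FALSE, quote = "",
                      colClasses = "character")
  } else {
    NULL
  }
  read_or_na <- function(path) {
    if (file.exists(path)) paste(readLines(path, warn = FALSE),
                                 collapse = "\n") else NA_character_
  }
  structure(list(
    fetch_run_xml = function(accession) {
      read_or_na(file.path(dir, paste0(accession, ".run.xml")))
    },
    fetch_biosample_xml = function(accession) {
      read_or_na(file.path(dir, paste0(accession, ".biosample.xml")))
    },
    fetch_api_row = function(accession) {
      if (is.null(api_tab) || !"run_accession" %in% names(api_tab)) {
        return(character(0))
      }
      i <- match(accession, api_tab$run_accession)
      if (is.na(i)) return(character(0))
      row <- unlist(api_tab[i, setdiff(names(api_tab), "run_accession"),
                            drop = TRUE])
      row[!is.na(row) & nzchar(row)]
    },
    dir = dir
  ), class = "fixture_fetcher")
}

#' Fetch and merge one run through a fetcher
#'
#' Convenience wrapper: run XML -> parse -> resolve BioSample -> BioSample
#' XML -> merge with the API row and optional user supplement.
#'
#' @param accession Run accession.
#' @param fetcher A fetcher (e.g. [fixture_fetcher()]).
#' @param user_supplement Optional mapping from [read_user_supplement()].
#' @return A merged `run_record`.
#' @export
fetch_run_record <- function(accession, fetcher, user_supplement = NULL) {
  run_xml <- fetcher$fetch_run_xml(accession)
  if (is.na(run_xml)) stop("no run XML available for ", accession)
  rec <- parse_run_xml(run_xml, accession = accession)
  bs_acc <- resolve_biosample_accession(rec, run_xml)
  bs_attrs <- character(0)
  if (!is.na(bs_acc)) {
    bs_xml <- fetcher$fetch_biosample_xml(bs_acc)
    if (is.na(bs_xml)) bs_xml <- fetcher$fetch_biosample_xml(accession)
    if (!is.na(bs_xml)) bs_attrs <- parse_biosample_xml(bs_xml)
  }
  api_row <- fetcher$fetch_api_row(accession)
  user_row <- if (!is.null(user_supplement)) {
    user_supplement[[accession]]
  } else {
    NULL
  }
  merge_sources(rec, biosample = bs_attrs, api_row = api_row,
                user_row = user_row, biosample_accession = bs_acc)
}
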