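#' Metadata class registry
#'
#' The pipeline reconstructs 19 metadata classes per SRA run. Four of them
#' (`study_accession`, `instrument_platform`, `number_of_base_pairs`,
#' `library_strategy`) are submission-mandatory and read directly from the
#' NCBI API record ("API-direct"); the remaining 15 are recovered from free
#' text by rules and, where rules abstain, by the language-model stage.
#'
#' Each class carries a value kind:
#' * `api_direct` — copied from API fields, never sent to the model;
#' * `discrete` — closed label set (e.g. `sequencing_source`:
#'   bulk / single cell / spatial);
#' * `boolean` — True/False (`is_cancer`);
#' * `open_vocab` — unbounded free text (organ, disease, ...), evaluated by
#'   context-tolerant matching;
#' * `numeric_or_qualitative` — `age`: a number in plausible human bounds or
#'   a qualitative term (child/teen/adult/senior).
#'
#' The registry ships as a TSV under `inst/extdata/classes.tsv` (columns
#' `name`, `kind`, `allowed_values` pipe-separated, `definition_text`,
#' `resolution_preference`) so the schema can be extended without code
#' changes.
#'
#' @param path Optional path to a registry TSV; defaults to the packaged one.
#' @return An object of class `class_registry`: a named list of
#'   `metadata_class` entries, in schema order.
#' @export
#' @examples
#' reg <- class_registry()
#' length(reg)                        # 19
#' names(api_direct_classes(reg))     # the four API-direct classes
class_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "classes.tsv", package = "sramend")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("class registry file not found: ", path)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                           colClasses = "character")
  needed <- c("name", "kind", "allowed_values", "definition_text",
              "resolution_preference")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("registry TSV lacks columns: ", paste(missing, collapse = ", "))
  }
  classes <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    allowed <- character(0)
    if (nzchar(row$allowed_values)) {
      allowed <- trimws(strsplit(row$allowed_values, "|", fixed = TRUE)[[1]])
      allowed <- allowed[nzchar(allowed)]
    }
    cls <- structure(
      list(
        name = row$name,
        kind = row$kind,
        allowed_values = allowed,
        definition_text = row$definition_text,
        resolution_preference = row$resolution_preference
      ),
      class = "metadata_class"
    )
    validate_metadata_class(cls)
    cls
  })
  names(classes) <- vapply(classes, `[[`, character(1), "name")
  reg <- structure(classes, class = "class_registry")
  validate_class_registry(reg)
  reg
}

validate_metadata_class <- function(cls) {
  kinds <- c("api_direct", "discrete", "open_vocab", "boolean",
             "numeric_or_qualitative")
  if (!cls$kind %in% kinds) {
    stop("class '", cls$name, "': unknown kind '", cls$kind, "'")
  }
  if (cls$kind %in% c("discrete", "boolean") && !length(cls$allowed_values)) {
    stop("class '", cls$name, "': ", cls$kind,
         " kind requires a non-empty allowed value set")
  }
  if (cls$kind != "api_direct" && !nzchar(cls$definition_text)) {
    stop("class '", cls$name, "': definition text required")
  }
  if (!cls$resolution_preference %in% c("rule", "llm")) {
    stop("class '", cls$name, "': resolution_preference must be rule or llm")
  }
  invisible(cls)
}

validate_class_registry <- function(reg) {
  if (length(reg) != 19L) {
    stop("registry must hold exactly 19 classes, found ", length(reg))
  }
  if (anyDuplicated(names(reg))) stop("duplicate class names in registry")
  api <- names(api_direct_classes(reg))
  if (!setequal(api, c("study_accession", "instrument_platform",
                       "number_of_base_pairs", "library_strategy"))) {
    stop("API-direct classes must be exactly the four mandatory fields")
  }
  if (length(llm_routed_classes(reg)) != 15L) {
    stop("exactly 15 classes must be routed to the model stage")
  }
  invisible(reg)
}

#' @export
print.class_registry <- function(x, ...) {
  cat("Metadata class registry:", length(x), "classes\n")
  for (cls in x) {
    av <- if (length(cls$allowed_values)) {
      paste0(" {", paste(cls$allowed_values, collapse = ", "), "}")
    } else ""
    cat(sprintf("  %-22s %-22s%s\n", cls$name, cls$kind, av))
  }
  invisible(x)
}

#' Subsets of the registry by routing
#'
#' `api_direct_classes()` returns the classes filled straight from the API
#' record; `llm_routed_classes()` the classes eligible for model completion
#' (everything else).
#'
#' @param registry A `class_registry`.
#' @return A named list of `metadata_class` entries.
#' @export
api_direct_classes <- function(registry) {
  registry[vapply(registry, function(c) c$kind == "api_direct", logical(1))]
}

#' @rdname api_direct_classes
#' @export
llm_routed_classes <- function(registry) {
  registry[vapply(registry, function(c) c$kind != "api_direct", logical(1))]
}

# Alias folding applied before closed-set validation. Sex abbreviations are
# the only defaults; extensible via the `aliases` argument of validate_value.
.default_value_aliases <- list(
  sex = c(m = "male", f = "female")
)

.qualitative_ages <- c("child", "teen", "adult", "senior")

#' Validate a raw value against a class contract
#'
#' Type-and-range checking as applied before any value enters the curated
#' table. Closed classes (discrete, boolean) accept only members of their
#' allowed set, case-insensitively, and return the canonical casing. `age`
#' must be numeric in \[0, 120\] (a range like "40-45" is accepted when both
#' ends are in bounds) or one of child/teen/adult/senior. `sex` folds
#' m/f abbreviations before the closed-set check. Open-vocabulary classes
#' accept any non-placeholder text. Rejection is a value, not an error: the
#' outcome carries a machine-readable reason.
#'
#' @param class A `metadata_class` entry.
#' @param raw A single non-NA string.
#' @param aliases Optional per-class alias tables overriding the defaults.
#' @return A list with `accepted` (flag), `normalized_value` (string or NA),
#'   and `reason` (string, NA when accepted).
#' @export
#' @examples
#' reg <- class_registry()
#' validate_value(reg$age, "42")
#' validate_value(reg$library_selection, "polya")  # canonicalized to "polyA"
validate_value <- function(class, raw, aliases = .default_value_aliases) {
  stopifnot(inherits(class, "metadata_class"))
  if (length(raw) != 1L || is.na(raw) || !is.character(raw)) {
    stop("raw must be a single non-NA string")
  }
  val <- squash_ws(raw)
  reject <- function(reason) {
    list(accepted = FALSE, normalized_value = NA_character_, reason = reason)
  }
  accept <- function(norm) {
    list(accepted = TRUE, normalized_value = norm, reason = NA_character_)
  }
  if (!nzchar(val)) return(reject("empty"))
  if (is_placeholder(val) &&
      !(tolower(val) == "unknown" &&
        "unknown" %in% tolower(class$allowed_values))) {
    return(reject("placeholder"))
  }

  alias_tab <- aliases[[class$name]]
  if (!is.null(alias_tab)) {
    hit <- match(tolower(val), tolower(names(alias_tab)))
    if (!is.na(hit)) val <- unname(alias_tab[[hit]])
  }

  if (class$kind %in% c("discrete", "boolean")) {
    hit <- match(tolower(val), tolower(class$allowed_values))
    if (is.na(hit)) return(reject("not_in_allowed_values"))
    return(accept(class$allowed_values[[hit]]))
  }

  if (class$kind == "numeric_or_qualitative") {
    low <- tolower(val)
    if (low %in% .qualitative_ages) return(accept(low))
    # single number or a dash range, e.g. "42", "42.5", "40-45"
    m <- regmatches(val, regexec(
      "^([0-9]+(?:\\.[0-9]+)?)(?:\\s*-\\s*([0-9]+(?:\\.[0-9]+)?))?$", val))[[1]]
    if (!length(m)) {
      if (grepl("^-", val)) return(reject("out_of_range"))
      return(reject("not_numeric_or_qualitative"))
    }
    ends <- as.numeric(m[-1][nzchar(m[-1])])
    if (any(ends < 0) || any(ends > 120)) return(reject("out_of_range"))
    return(accept(val))
  }

  # api_direct and open_vocab: any non-placeholder text stands
  accept(val)
}

#' Split a possibly multi-valued answer into an ordered value set
#'
#' Model answers and free-text fields may list several values separated by
#' "," or ";". Splits on both, trims whitespace, drops empties, and
#' deduplicates preserving first-occurrence order. Idempotent on its own
#' output rendered with `", "`.
#'
#' @param raw A string.
#' @return Character vector of distinct trimmed values (possibly empty).
#' @export
#' @examples
#' parse_multi_value("lung, liver; lung")  # c("lung", "liver")
parse_multi_value <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (is.na(raw)) return(character(0))
  parts <- trimws(strsplit(raw, "[,;]")[[1]])
  parts <- parts[nzchar(parts)]
  unique(parts)
}

# Placeholder strings treated as absent content everywhere.
.placeholder_values <- c(
  "unknown", "missing", "not collected", "not applicable", "na", "n/a",
  "none", "not provided", "not available", "null", "--", "-"
)

is_placeholder <- function(x) {
  tolower(trimws(x)) %in% .placeholder_values
}

squash_ws <- function(x) {
  gsub("\\s+", " ", trimws(x))
}
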