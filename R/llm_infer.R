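#' The fixed instruction block appended to every prompt
#'
#' Extract-if-possible, return "unknown" when a value cannot be extracted
#' even by deduction, a per-run disambiguation warning (study text may
#' describe several samples), and the multi-answer separators ("," or ";").
#'
#' @return A single string.
#' @export
prompt_instruction_block <- function() {
  paste(
    "Extract information from the summary if possible.",
    "If one value is impossible to extract, even by deducing it, return",
    "\"unknown\".",
    "Be careful: sometimes the information concerns several samples from the",
    "same study. Distinguish what applies to the current run so everything",
    "remains consistent. For each class, several answers can be possible;",
    "cite them all with a \",\" or \";\" separator."
  )
}

#' Assemble the per-class prompt for one run
#'
#' Four blocks in fixed order: (a) the run accession, (b) the context
#' summary plus any ambiguity notes from preprocessing, (c) the single
#' class definition line taken verbatim from the registry, (d) the
#' instruction block. Exactly one class definition per prompt — one class
#' is asked at a time. API-direct classes are never prompted.
#'
#' @param run Run accession.
#' @param bundle A (summarized) `context_bundle`.
#' @param class A non-API-direct `metadata_class`.
#' @return A `prompt` object; `format()`/`print()` render the full text.
#' @export
build_prompt <- function(run, bundle, class) {
  stopifnot(inherits(bundle, "context_bundle"),
            inherits(class, "metadata_class"))
  if (class$kind == "api_direct") {
    stop("class '", class$name,
         "' is API-direct and is never routed to the model")
  }
  structure(list(
    run_accession = run,
    summary_text = bundle_text(bundle),
    ambiguity_text = paste(bundle$ambiguity_notes, collapse = " "),
    class_name = class$name,
    class_definition_line = paste0("- ", class$name, ": ",
                                   class$definition_text),
    instruction_block = prompt_instruction_block()
  ), class = "prompt")
}

#' @export
format.prompt <- function(x, ...) {
  amb <- if (nzchar(x$ambiguity_text)) {
    paste0("\nAmbiguity notes: ", x$ambiguity_text)
  } else ""
  paste0(
    "Run accession: ", x$run_accession, "\n",
    "Context summary: ", x$summary_text, amb, "\n",
    x$class_definition_line, "\n",
    x$instruction_block
  )
}

#' @export
print.prompt <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Select the adapter for a class
#'
#' One task adapter per class: the backend activates the class's adapter on
#' the frozen base model at inference. Pure configuration lookup — when no
#' adapter is configured for the class, the base model identifier is
#' returned.
#'
#' @param class A model-routed `metadata_class`.
#' @param config List with optional `adapter_map` (class -> adapter id) and
#'   `base_model` (default `"base"`).
#' @return Adapter identifier string.
#' @export
route_adapter <- function(class, config = list()) {
  stopifnot(inherits(class, "metadata_class"))
  if (class$kind == "api_direct") {
    stop("class '", class$name, "' is not routed to the model")
  }
  map <- config$adapter_map
  if (!is.null(map) && class$name %in% names(map)) {
    return(map[[class$name]])
  }
  if (!is.null(config$base_model)) return(config$base_model)
  "base"
}

#' Confidence from per-token log-probabilities
#'
#' The two per-prediction confidence scores: mean negative log-likelihood
#' over the generated answer tokens (nats/token) and its exponential, the
#' perplexity. `ppl == exp(mean_nll)` by construction.
#'
#' @param logprobs Non-empty numeric vector of per-token log-probabilities
#'   (each <= 0).
#' @return `list(mean_nll=, ppl=)`, class `confidence`.
#' @export
#' @examples
#' confidence_from_logprobs(c(-1, -3))  # mean_nll 2, ppl exp(2)
confidence_from_logprobs <- function(logprobs) {
  if (!length(logprobs) || !is.numeric(logprobs)) {
    stop("logprobs must be a non-empty numeric vector")
  }
  if (any(logprobs > 1e-12)) {
    stop("log-probabilities must be <= 0")
  }
  mean_nll <- -mean(logprobs)
  structure(list(mean_nll = mean_nll, ppl = exp(mean_nll)),
            class = "confidence")
}

#' Mock inference backend
#'
#' A deterministic stand-in for the model stage, enabling end-to-end and
#' evaluation tests without weights. It resolves the truth for a
#' (run, class) pair from the machine-readable marker table emitted by the
#' synthetic generator (keyed by the run accession found in prompt block
#' (a)), then perturbs the answer with configurable, seeded noise: with
#' probability `abstention_rate` it answers "unknown"; with probability
#' `substitution_rate` it substitutes a wrong label (another member of the
#' allowed set for closed classes, a decoy string for open vocabulary);
#' otherwise it returns the truth. Token log-probabilities are synthesized
#' so that clean answers score more confident (lower NLL) than perturbed
#' ones. Deterministic given (prompt, seed).
#'
#' @param truth Named list: accession -> named list class -> character
#'   vector of true values (as produced by [truth_table()]), or a marker
#'   string per accession (see [parse_hidden_marker()]).
#' @param registry A `class_registry` (for closed label sets).
#' @param substitution_rate,abstention_rate Noise rates in \[0, 1\].
#' @param seed Integer seed.
#' @return A `backend` object with a `generate(prompt)` function and
#'   identity metadata.
#' @export
mock_backend <- function(truth, registry = class_registry(),
                         substitution_rate = 0, abstention_rate = 0,
                         seed = 1L) {
  stopifnot(substitution_rate >= 0, abstention_rate >= 0,
            substitution_rate + abstention_rate <= 1)
  truth <- lapply(truth, function(t) {
    if (is.character(t) && is.null(names(t)) && length(t) == 1L) {
      parse_hidden_marker(t)
    } else {
      t
    }
  })
  generate <- function(prompt) {
    stopifnot(inherits(prompt, "prompt"))
    acc <- prompt$run_accession
    cls_name <- prompt$class_name
    tr <- truth[[acc]][[cls_name]]
    if (is.null(tr) || !length(tr)) tr <- "unknown"
    # per-(accession, class) substream, independent of call order
    u <- local_runif(seed, acc, cls_name, n = 2L)
    answer <- tr
    clean <- TRUE
    if (u[1] < abstention_rate) {
      answer <- "unknown"
      clean <- identical(tr, "unknown")
    } else if (u[1] < abstention_rate + substitution_rate) {
      answer <- substitute_label(tr, registry[[cls_name]], u[2])
      clean <- FALSE
    }
    text <- paste(answer, collapse = ", ")
    ntok <- max(1L, count_tokens(text))
    base_lp <- if (clean) -0.05 else -1.2
    lp <- rep(base_lp * (0.8 + 0.4 * u[2]), ntok)
    list(text = text, logprobs = lp)
  }
  structure(list(generate = generate, model_name = "mock", adapter_id = "mock",
                 substitution_rate = substitution_rate,
                 abstention_rate = abstention_rate, seed = seed),
            class = "backend")
}

# Seeded uniforms from a (seed, accession, class) key without touching the
# global RNG stream ordering guarantees.
local_runif <- function(seed, acc, cls, n = 1L) {
  key <- sum(utf8ToInt(paste0(acc, "\r", cls)) *
               seq_along(utf8ToInt(paste0(acc, "\r", cls))))
  sub_seed <- (as.numeric(seed) * 69069 + key) %% 2147483647
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(sub_seed))
  stats::runif(n)
}

substitute_label <- function(truth_vals, class, u) {
  if (!is.null(class) && length(class$allowed_values)) {
    pool <- setdiff(class$allowed_values, truth_vals)
    if (!length(pool)) return(truth_vals)
    return(pool[[1L + floor(u * length(pool)) %% length(pool)]])
  }
  paste0("not ", truth_vals[[1]])
}

#' Run one class through a backend
#'
#' Calls the backend, strips whitespace and surrounding quotes, splits
#' multi-valued answers, snaps closed-class outputs to the nearest allowed
#' label by case-insensitive exact match (anything else becomes "unknown"
#' with a warning flag — no fuzzy snapping, to avoid silent label
#' corruption), attaches NLL/PPL confidence, and never lets "unknown"
#' co-occur with real values. A backend failure degrades to an "unknown"
#' prediction with the failure flagged, not an error.
#'
#' @param backend A `backend`.
#' @param prompt A `prompt` built by [build_prompt()].
#' @param class The `metadata_class` being predicted.
#' @return A `prediction`: class name, ordered value set, confidence,
#'   raw text, flags.
#' @export
infer_class <- function(backend, prompt, class) {
  stopifnot(inherits(backend, "backend"), inherits(prompt, "prompt"),
            inherits(class, "metadata_class"))
  out <- tryCatch(backend$generate(prompt), error = function(e) e)
  flags <- character(0)
  if (inherits(out, "error")) {
    return(structure(list(
      class_name = class$name, values = "unknown",
      confidence = structure(list(mean_nll = NA_real_, ppl = NA_real_),
                             class = "confidence"),
      raw_text = NA_character_, flags = "backend_failure"
    ), class = "prediction"))
  }
  raw <- out$text
  txt <- gsub('^[\'"\\s]+|[\'"\\s]+$', "", trimws(raw), perl = TRUE)
  vals <- parse_multi_value(txt)
  if (!length(vals)) vals <- "unknown"
  if (class$kind %in% c("discrete", "boolean")) {
    snapped <- character(0)
    for (v in vals) {
      hit <- match(tolower(v), tolower(class$allowed_values))
      if (!is.na(hit)) {
        snapped <- c(snapped, class$allowed_values[[hit]])
      } else if (tolower(v) == "unknown") {
        snapped <- c(snapped, "unknown")
      } else {
        flags <- c(flags, paste0("unparseable_label:", v))
      }
    }
    vals <- if (length(snapped)) unique(snapped) else "unknown"
  }
  if ("unknown" %in% vals && length(vals) > 1L) {
    vals <- setdiff(vals, "unknown")
  }
  structure(list(
    class_name = class$name, values = vals,
    confidence = confidence_from_logprobs(out$logprobs),
    raw_text = raw, flags = flags
  ), class = "prediction")
}

#' Run every model-routed class for one run
#'
#' @param backend A `backend`.
#' @param run Run accession.
#' @param bundle Summarized `context_bundle`.
#' @param registry A `class_registry`.
#' @param config Adapter routing configuration (see [route_adapter()]).
#' @return Named list of `prediction`s, one per model-routed class.
#' @export
infer_run <- function(backend, run, bundle, registry = class_registry(),
                      config = list()) {
  classes <- llm_routed_classes(registry)
  preds <- lapply(classes, function(cls) {
    prompt <- build_prompt(run, bundle, cls)
    infer_class(backend, prompt, cls)
  })
  names(preds) <- names(classes)
  preds
}

#' Write / read per-run prediction files
#'
#' One JSON file per run holding all 15 model-routed class predictions with
#' both confidence scores each; `read_prediction_file()` reloads them
#' losslessly.
#'
#' @param run Run accession.
#' @param predictions Named list of `prediction`s covering every
#'   model-routed class.
#' @param path Output file path.
#' @param registry A `class_registry` used to check coverage.
#' @return `path`, invisibly.
#' @export
write_prediction_file <- function(run, predictions, path,
                                  registry = class_registry()) {
  expect <- names(llm_routed_classes(registry))
  have <- vapply(predictions, `[[`, character(1), "class_name")
  missing <- setdiff(expect, have)
  if (length(missing)) {
    stop("predictions missing for classes: ", paste(missing, collapse = ", "))
  }
  payload <- list(
    run_accession = run,
    predictions = lapply(unname(predictions), function(p) {
      list(class_name = p$class_name, values = as.list(p$values),
           mean_nll = p$confidence$mean_nll, ppl = p$confidence$ppl,
           raw_text = p$raw_text, flags = as.list(p$flags))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_prediction_file
#' @return `read_prediction_file()`: `list(run_accession=, predictions=)`
#'   with the same structure as written.
#' @export
read_prediction_file <- function(path) {
  payload <- jsonlite::read_json(path)
  preds <- lapply(payload$predictions, function(p) {
    structure(list(
      class_name = p$class_name,
      values = as.character(unlist(p$values)),
      confidence = structure(
        list(mean_nll = null_to_na(p$mean_nll), ppl = null_to_na(p$ppl)),
        class = "confidence"),
      raw_text = null_to_na(p$raw_text),
      flags = as.character(unlist(p$flags))
    ), class = "prediction")
  })
  names(preds) <- vapply(preds, `[[`, character(1), "class_name")
  list(run_accession = payload$run_accession, predictions = preds)
}

null_to_na <- function(x) if (is.null(x)) NA else x
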