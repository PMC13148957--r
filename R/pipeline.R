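#' Annotate runs end to end
#'
#' The full offline pipeline for a fixture directory (or any fetcher):
#' fetch and merge each run's sources, build and budget the context,
#' run the deterministic rule stage, complete the remaining classes through
#' the backend, resolve rule and model values under the chosen policy, and
#' post-propagate/normalize. With the mock backend and a fixed seed the
#' output is bit-reproducible.
#'
#' @param accessions Run accessions; default: every run in the fixture dir.
#' @param fixtures Fixture directory (see [write_fixture_dir()]); ignored
#'   when `fetcher` is given.
#' @param fetcher Optional fetcher overriding `fixtures`.
#' @param backend A `backend`; default: mock backend answering from the
#'   fixture truth table (noise-free).
#' @param policy Resolution policy, see [resolve_row()].
#' @param token_budget Context token budget (default 2000).
#' @param registry,lexicons Schema and lexicons.
#' @param user_supplement Optional mapping from [read_user_supplement()].
#' @param prediction_dir Optional directory to write per-run prediction
#'   JSON files into.
#' @return Named list of resolved `annotation_row`s, one per accession.
#' @export
annotate_runs <- function(accessions = NULL, fixtures = NULL, fetcher = NULL,
                          backend = NULL,
                          policy = c("locked", "per_class_preference"),
                          token_budget = 2000L,
                          registry = class_registry(),
                          lexicons = load_lexicons(),
                          user_supplement = NULL,
                          prediction_dir = NULL) {
  policy <- match.arg(policy)
  if (is.null(fetcher)) {
    if (is.null(fixtures)) stop("either fixtures or fetcher is required")
    fetcher <- fixture_fetcher(fixtures)
  }
  if (is.null(accessions)) {
    if (is.null(fixtures)) stop("accessions required when no fixture dir")
    accessions <- sort(sub("\\.run\\.xml$", "",
                           basename(list.files(fixtures,
                                               pattern = "\\.run\\.xml$"))))
  }
  if (is.null(backend)) {
    if (is.null(fixtures) || !file.exists(file.path(fixtures, "truth.tsv"))) {
      stop("no backend given and no fixture truth table to mock from")
    }
    backend <- mock_backend(read_truth_tsv(fixtures), registry)
  }
  out <- list()
  for (acc in accessions) {
    row <- tryCatch({
      rec <- fetch_run_record(acc, fetcher, user_supplement)
      curated <- run_rule_stage(rec, lexicons = lexicons,
                                registry = registry)
      bundle <- build_context(rec, ambiguity_notes = curated$notes)
      bundle <- summarize_context(bundle, budget = token_budget)
      preds <- infer_run(backend, acc, bundle, registry)
      if (!is.null(prediction_dir)) {
        dir.create(prediction_dir, showWarnings = FALSE, recursive = TRUE)
        write_prediction_file(acc, preds,
                              file.path(prediction_dir,
                                        paste0(acc, ".json")),
                              registry)
      }
      resolved <- resolve_row(curated, preds, policy = policy,
                              registry = registry)
      post_propagate(resolved, lexicons)
    }, error = function(e) {
      message("run ", acc, " failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(row)) out[[acc]] <- row
  }
  out
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `inst/cli/sramend` Rscript wrapper. Commands:
#' `fetch` (resolve accessions against a fixture directory and write the
#' merged per-run TSV), `annotate` (full pipeline to an exported table),
#' `simulate` (generate a pool, split it, write fixtures), `evaluate`
#' (score an annotated table against a truth table), `report` (summary
#' statistics of an annotated table). Every command works offline with
#' `--fixtures`. Returns instead of calling `quit()` so it is testable.
#'
#' @param args Character vector of command-line arguments (first element:
#'   the command).
#' @return Exit status, invisibly (0 on success).
#' @export
run_command <- function(args) {
  if (!length(args) || args[[1]] %in% c("-h", "--help")) {
    cat(cli_usage())
    return(invisible(0L))
  }
  command <- args[[1]]
  status <- tryCatch({
    opts <- parse_cli_flags(args[-1])
    switch(command,
      fetch = cli_fetch(opts),
      annotate = cli_annotate(opts),
      simulate = cli_simulate(opts),
      evaluate = cli_evaluate(opts),
      report = cli_report(opts),
      {
        message("unknown command: ", command)
        cat(cli_usage())
        return(invisible(2L))
      }
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cli_usage <- function() {
  paste(
    "usage: sramend <command> [--flag value ...]",
    "",
    "commands:",
    "  fetch     --fixtures DIR --out FILE [--accessions A,B,...]",
    "  annotate  --fixtures DIR --out PREFIX [--backend mock]",
    "            [--resolution-policy locked|per_class_preference]",
    "            [--token-budget N] [--formats csv,tsv,json] [--seed N]",
    "            [--supplement FILE] [--lexicon-dir DIR]",
    "  simulate  --n N --seed N --out DIR [--reference-n N]",
    "  evaluate  --fixtures DIR --table FILE --out FILE",
    "  report    --table FILE --out FILE",
    "", sep = "\n")
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      stop("flag ", a, " requires a value")
    }
    opts[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  opts
}

opt_or <- function(opts, key, default) {
  if (!is.null(opts[[key]])) opts[[key]] else default
}

cli_lexicons <- function(opts) {
  if (!is.null(opts$lexicon_dir)) load_lexicons(opts$lexicon_dir) else
    load_lexicons()
}

cli_fetch <- function(opts) {
  if (is.null(opts$fixtures) || is.null(opts$out)) {
    stop("fetch requires --fixtures and --out")
  }
  fetcher <- fixture_fetcher(opts$fixtures)
  accs <- if (!is.null(opts$accessions)) {
    strsplit(opts$accessions, ",", fixed = TRUE)[[1]]
  } else {
    sort(sub("\\.run\\.xml$", "",
             basename(list.files(opts$fixtures,
                                 pattern = "\\.run\\.xml$"))))
  }
  recs <- lapply(accs, fetch_run_record, fetcher = fetcher)
  df <- do.call(rbind, lapply(recs, function(r) {
    data.frame(run_accession = r$run_accession,
               biosample_accession = r$biosample_accession,
               n_values = n_stored_values(r), stringsAsFactors = FALSE)
  }))
  utils::write.table(df, opts$out, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  message("fetched ", nrow(df), " runs -> ", opts$out)
}

cli_annotate <- function(opts) {
  if (is.null(opts$fixtures) || is.null(opts$out)) {
    stop("annotate requires --fixtures and --out")
  }
  lex <- cli_lexicons(opts)
  supp <- if (!is.null(opts$supplement)) {
    read_user_supplement(opts$supplement)
  } else {
    NULL
  }
  backend_name <- opt_or(opts, "backend", "mock")
  backend <- if (backend_name == "mock") NULL else
    stop("backend '", backend_name,
         "' is not available in this build; use 'mock'")
  rows <- annotate_runs(
    fixtures = opts$fixtures,
    backend = backend,
    policy = opt_or(opts, "resolution_policy", "locked"),
    token_budget = as.integer(opt_or(opts, "token_budget", "2000")),
    lexicons = lex,
    user_supplement = supp)
  formats <- strsplit(opt_or(opts, "formats", "tsv"), ",", fixed = TRUE)[[1]]
  paths <- export_table(rows, formats = formats, path_prefix = opts$out)
  message("annotated ", length(rows), " runs -> ",
          paste(paths, collapse = ", "))
}

cli_simulate <- function(opts) {
  if (is.null(opts$out)) stop("simulate requires --out")
  n <- as.integer(opt_or(opts, "n", "2000"))
  seed <- as.integer(opt_or(opts, "seed", "1"))
  ref_n <- as.integer(opt_or(opts, "reference_n", "200"))
  lex <- cli_lexicons(opts)
  cfg <- generation_config(lex)
  pool <- generate_pool(n, seed = seed, config = cfg, lexicons = lex)
  ref <- generate_pool(ref_n, seed = seed + 1L, config = cfg, lexicons = lex,
                       reference = TRUE)
  sizes <- round(c(0.2, 0.6, 0.2) * n)
  sizes[2] <- n - sizes[1] - sizes[3]
  splits <- split_by_proximity(pool, ref, sizes = sizes)
  write_fixture_dir(pool, opts$out)
  split_df <- do.call(rbind, lapply(names(splits), function(nm) {
    data.frame(run_accession = vapply(splits[[nm]], `[[`, character(1),
                                      "run_accession"),
               split = nm, stringsAsFactors = FALSE)
  }))
  utils::write.table(split_df, file.path(opts$out, "splits.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  message("simulated ", n, " samples (splits ",
          paste(vapply(splits, length, integer(1)), collapse = "/"),
          ") -> ", opts$out)
}

cli_evaluate <- function(opts) {
  if (is.null(opts$fixtures) || is.null(opts$table) || is.null(opts$out)) {
    stop("evaluate requires --fixtures, --table and --out")
  }
  truths <- read_truth_tsv(opts$fixtures)
  tab <- read_exported_table(opts$table)
  registry <- class_registry()
  preds <- lapply(seq_len(nrow(tab)), function(i) {
    vals <- lapply(intersect(names(registry), names(tab)), function(cn) {
      parse_multi_value(as.character(tab[[cn]][i]))
    })
    names(vals) <- intersect(names(registry), names(tab))
    vals
  })
  names(preds) <- tab$run_accession
  report <- evaluation_report(preds, truths, lexicons = cli_lexicons(opts))
  write_evaluation_tsv(report, opts$out)
  message("evaluation report -> ", opts$out)
}

cli_report <- function(opts) {
  if (is.null(opts$table) || is.null(opts$out)) {
    stop("report requires --table and --out")
  }
  tab <- read_exported_table(opts$table)
  registry <- class_registry()
  cls <- intersect(names(registry), names(tab))
  fill <- vapply(cls, function(cn) {
    mean(!vapply(as.character(tab[[cn]]), is_placeholder, logical(1)))
  }, numeric(1))
  df <- data.frame(class = cls, fill_rate = unname(fill),
                   stringsAsFactors = FALSE)
  utils::write.table(df, opts$out, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  message("summary -> ", opts$out)
}
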