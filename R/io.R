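#' Read registry records from a delimited file
#'
#' Expects a comma- or tab-delimited UTF-8 file with header columns
#' `patient_id`, `record_id`, `record_date`, `text`. Dates are ISO-8601
#' (`YYYY-MM-DD`) or empty (absent); invalid calendar dates are a
#' row-level error naming the line. Text is preserved verbatim:
#' normalization happens downstream in the matcher.
#'
#' @param path Input file path.
#' @return Data frame with `record_date` as `Date` (`NA` when absent).
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop(sprintf("records file not found: %s", path), call. = FALSE)
  df <- read_delimited(path)
  need <- c("patient_id", "record_id", "record_date", "text")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("records file %s is missing column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (any(!nzchar(df$patient_id)) || any(!nzchar(df$record_id))) {
    bad <- which(!nzchar(df$patient_id) | !nzchar(df$record_id))[1]
    stop(sprintf("empty patient_id/record_id at line %d of %s", bad + 1L, path),
         call. = FALSE)
  }
  dates <- rep(as.Date(NA), nrow(df))
  has <- nzchar(trimws(df$record_date))
  if (any(has)) {
    raw <- trimws(df$record_date[has])
    ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", raw)
    parsed <- as.Date(rep(NA_character_, length(raw)))
    parsed[ok] <- as.Date(raw[ok], format = "%Y-%m-%d", optional = TRUE)
    # as.Date with format silently rolls or NAs bad dates; re-format to
    # catch invalid calendar dates like 2013-02-30
    ok <- ok & !is.na(parsed) & format(parsed, "%Y-%m-%d") == raw
    if (any(!ok)) {
      line <- which(has)[which(!ok)[1]] + 1L
      stop(sprintf("unparseable record_date '%s' at line %d of %s",
                   raw[which(!ok)[1]], line, path), call. = FALSE)
    }
    dates[has] <- parsed
  }
  data.frame(patient_id = df$patient_id, record_id = df$record_id,
             record_date = dates, text = df$text, stringsAsFactors = FALSE)
}

#' Read a patient label file
#'
#' Delimited file with header `patient_id`, `group`; groups must be
#' among the eight labels of [treatment_groups()].
#'
#' @param path Input file path.
#' @return Data frame with `patient_id`, `group`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop(sprintf("label file not found: %s", path), call. = FALSE)
  df <- read_delimited(path)
  miss <- setdiff(c("patient_id", "group"), names(df))
  if (length(miss)) {
    stop(sprintf("label file %s is missing column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  bad <- setdiff(unique(df$group), TREATMENT_GROUPS)
  if (length(bad)) {
    stop(sprintf("label file %s has unknown group(s): %s",
                 path, paste(bad, collapse = ", ")), call. = FALSE)
  }
  data.frame(patient_id = df$patient_id, group = df$group,
             stringsAsFactors = FALSE)
}

#' Build a run configuration
#'
#' Bundles and validates the options shared by the command entry points.
#'
#' @param input_path Records file (or, with `counts_only = TRUE` in
#'   [cmd_evaluate()], a per-group counts file).
#' @param output_path Output path prefix (files get suffixes).
#' @param lexicon_path,phrase_path Optional custom lexicon; the packaged
#'   default lexicon is used when `NULL`.
#' @param gold_path Optional gold label file (required by evaluate).
#' @param mode `"faithful"` or `"strict"` classification mode.
#' @param negation_window Phrase scope window in characters.
#' @param ci_method `"wilson"`, `"wald"`, or `"exact"`.
#' @param date_policy `"undated-first"` or `"undated-last"`.
#' @param counts_only Evaluate directly from 2x2 counts.
#' @param seed Integer seed (simulate).
#' @param n_patients Cohort size (simulate).
#' @param log_level `"info"` or `"quiet"`.
#' @return A list of class `ct_run_config`.
#' @export
run_config <- function(input_path = NULL, output_path = NULL,
                       lexicon_path = NULL, phrase_path = NULL,
                       gold_path = NULL,
                       mode = c("faithful", "strict"),
                       negation_window = 40L,
                       ci_method = c("wilson", "wald", "exact"),
                       date_policy = c("undated-first", "undated-last"),
                       counts_only = FALSE, seed = 1L, n_patients = 1000L,
                       log_level = c("info", "quiet")) {
  structure(list(input_path = input_path, output_path = output_path,
                 lexicon_path = lexicon_path, phrase_path = phrase_path,
                 gold_path = gold_path, mode = match.arg(mode),
                 negation_window = as.integer(negation_window),
                 ci_method = match.arg(ci_method),
                 date_policy = match.arg(date_policy),
                 counts_only = isTRUE(counts_only),
                 seed = as.integer(seed), n_patients = as.integer(n_patients),
                 log_level = match.arg(log_level)),
            class = "ct_run_config")
}

run_lexicon <- function(run) {
  if (is.null(run$lexicon_path)) default_lexicon()
  else load_lexicon(run$lexicon_path, run$phrase_path,
                    version = basename(run$lexicon_path))
}

run_log <- function(run, fmt, ...) {
  if (run$log_level != "quiet") message(sprintf(fmt, ...))
  invisible(NULL)
}

#' Classify a records file and write labeled output
#'
#' Reads records, classifies the cohort, and writes three files under
#' the output prefix: `<out>_records.csv` (per-record label, rule fired,
#' and mention evidence), `<out>_patients.csv` (patient-level first-line
#' labels), and `<out>_log.txt` (lexicon version and per-group counts).
#' Deterministic: identical input produces identical output files.
#'
#' @param run A `ct_run_config` with `input_path` and `output_path` set.
#' @return Invisibly, the patient-level data frame.
#' @export
cmd_classify <- function(run) {
  stopifnot(inherits(run, "ct_run_config"))
  if (is.null(run$input_path) || is.null(run$output_path)) {
    stop("cmd_classify needs input_path and output_path", call. = FALSE)
  }
  lex <- run_lexicon(run)
  matcher <- compile_lexicon(lex)
  records <- read_records(run$input_path)
  patients <- classify_cohort(records, matcher, mode = run$mode,
                              negation_window = run$negation_window,
                              date_policy = run$date_policy,
                              keep_record_level = TRUE)
  rec_df <- attr(patients, "records")
  attr(patients, "records") <- NULL
  utils::write.csv(rec_df, paste0(run$output_path, "_records.csv"),
                   row.names = FALSE, quote = TRUE)
  utils::write.csv(patients, paste0(run$output_path, "_patients.csv"),
                   row.names = FALSE, quote = TRUE)
  counts <- table(factor(patients$group, levels = TREATMENT_GROUPS))
  writeLines(c(
    sprintf("lexicon_version: %s", lex$version),
    sprintf("mode: %s", run$mode),
    sprintf("n_records: %d", nrow(records)),
    sprintf("n_patients: %d", nrow(patients)),
    sprintf("group_count.%s: %d", names(counts), as.integer(counts))),
    paste0(run$output_path, "_log.txt"))
  run_log(run, "classified %d records / %d patients", nrow(records), nrow(patients))
  invisible(patients)
}

#' Evaluate algorithm labels against a gold standard and write the report
#'
#' Default mode reads a predictions label file (`input_path`) and a gold
#' label file (`gold_path`) and writes the full eight-group report (the
#' shape of a published registry validation: contingency counts,
#' agreement, kappa, sensitivity/specificity/PPV/NPV, error counts) to
#' `<out>_report.txt`. With `counts_only = TRUE`, `input_path` is
#' instead a per-group counts file with header `group,tp,fp,fn,tn`.
#'
#' @param run A `ct_run_config`.
#' @return Invisibly, the `ct_eval_report`.
#' @export
cmd_evaluate <- function(run) {
  stopifnot(inherits(run, "ct_run_config"))
  if (is.null(run$input_path) || is.null(run$output_path)) {
    stop("cmd_evaluate needs input_path and output_path", call. = FALSE)
  }
  report <- if (run$counts_only) {
    evaluate_counts(read_delimited(run$input_path), ci_method = run$ci_method)
  } else {
    if (is.null(run$gold_path)) {
      stop("cmd_evaluate needs gold_path (or counts_only = TRUE)", call. = FALSE)
    }
    evaluate(read_labels(run$input_path), read_labels(run$gold_path),
             ci_method = run$ci_method)
  }
  writeLines(format_eval_report(report), paste0(run$output_path, "_report.txt"))
  run_log(run, "evaluation report written for n = %d patients", report$n)
  invisible(report)
}

#' Generate a synthetic corpus and write it to files
#'
#' Writes `<out>_records.csv`, `<out>_gold.csv`, and `<out>_config.txt`
#' (a key-value echo of the generator configuration). Reproducible from
#' the seed.
#'
#' @param run A `ct_run_config` with `output_path`, `seed`, `n_patients`.
#' @param config Optional full `ct_sim_config`; overrides `seed` and
#'   `n_patients` from `run`.
#' @return Invisibly, the generated `ct_corpus`.
#' @export
cmd_simulate <- function(run, config = NULL) {
  stopifnot(inherits(run, "ct_run_config"))
  if (is.null(run$output_path)) stop("cmd_simulate needs output_path", call. = FALSE)
  if (is.null(config)) {
    config <- simulation_config(n_patients = run$n_patients, seed = run$seed)
  }
  corpus <- generate_corpus(config)
  write_corpus(corpus,
               paste0(run$output_path, "_records.csv"),
               paste0(run$output_path, "_gold.csv"),
               paste0(run$output_path, "_config.txt"))
  run_log(run, "simulated %d records / %d patients",
          nrow(corpus$records), nrow(corpus$gold))
  invisible(corpus)
}
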