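TREATMENT_GROUPS <- c("tki", "pem_bev", "pemetrexed_based", "bevacizumab_based",
                      "platinum_doublet", "single_agent", "no_treatment", "unknown")
DRUG_GROUPS <- TREATMENT_GROUPS[1:6]

#' The eight treatment-group labels
#'
#' In search-precedence order: `tki`, `pem_bev`, `pemetrexed_based`,
#' `bevacizumab_based`, `platinum_doublet`, `single_agent`,
#' `no_treatment`, `unknown`. The first six are drug-defined groups; the
#' last two capture explicit no-treatment statements and blank or
#' non-informative text.
#'
#' @return Character vector of length eight.
#' @export
treatment_groups <- function() TREATMENT_GROUPS

#' Assign a treatment group to one record's mention evidence
#'
#' Applies the fixed search precedence that the registry algorithm
#' expresses as sequential elimination: groups are tried from the most
#' specific drug sets to the broadest, and the first rule whose drug
#' evidence is present wins. Negated mentions must be excluded before
#' calling (see [classify_record()], which does this). Distinctness is by
#' canonical drug name, not mention count, so "carboplatin ...
#' carboplatin" is a single agent, not a doublet.
#'
#' Precedence: (1) any TKI; (2) pemetrexed and bevacizumab together;
#' (3) pemetrexed (alone or with platinum/other chemo); (4) bevacizumab
#' (alone or with platinum/other chemo); (5) a platinum plus a distinct
#' other chemotherapy drug; (6) any remaining drug evidence (single
#' agent); (7) an explicit no-treatment statement; (8) unknown.
#'
#' In `faithful` mode (default) rule 6 absorbs multi-drug non-platinum
#' combinations, mirroring the published algorithm's broad final drug
#' search; in `strict` mode such records fall through to `unknown`.
#'
#' @param mentions Mention data frame (non-negated; in `strict` mode
#'   uncertain mentions should also have been removed upstream).
#' @param no_treatment_flag Result of [detect_no_treatment()].
#' @param mode `"faithful"` or `"strict"`.
#' @return A single group label.
#' @export
#' @examples
#' m <- compile_lexicon(default_lexicon())
#' assign_group(find_mentions("cisplatin + gemcitabine", m), FALSE)
assign_group <- function(mentions, no_treatment_flag, mode = c("faithful", "strict")) {
  mode <- match.arg(mode)
  cls <- unique(mentions$drug_class)
  canon <- unique(mentions$canonical)
  if ("tki" %in% cls) return("tki")
  has_pem <- "pemetrexed" %in% cls
  has_bev <- "bevacizumab" %in% cls
  if (has_pem && has_bev) return("pem_bev")
  if (has_pem) return("pemetrexed_based")
  if (has_bev) return("bevacizumab_based")
  has_plat <- "platinum" %in% cls
  n_other <- length(unique(mentions$canonical[mentions$drug_class == "other_chemo"]))
  if (has_plat && n_other >= 1L) return("platinum_doublet")
  if (length(canon) >= 1L) {
    if (mode == "faithful" || length(canon) == 1L) return("single_agent")
    # strict: multiple non-platinum-doublet drugs are not a defined group
    return("unknown")
  }
  if (isTRUE(no_treatment_flag)) return("no_treatment")
  "unknown"
}

#' Classify a single record
#'
#' Pipeline: normalize the text, find mentions, drop negated mentions
#' (and uncertain ones in `strict` mode), detect whole-record
#' no-treatment statements, then apply the precedence rules of
#' [assign_group()]. Blank or non-informative text yields `unknown`.
#'
#' @param record One-row data frame or list with `record_id` and `text`.
#' @param matcher A `ct_matcher`.
#' @param mode `"faithful"` (default) or `"strict"`.
#' @param negation_window Phrase scope window in characters.
#' @return A list of class `ct_record_class` with `record_id`, `group`,
#'   `rule_fired` (audit trail naming the precedence stage), and
#'   `mentions` (all mentions, including negated ones, as evidence).
#' @export
classify_record <- function(record, matcher, mode = c("faithful", "strict"),
                            negation_window = 40L) {
  mode <- match.arg(mode)
  text <- normalize_text(if (is.character(record)) record[1] else record$text[[1]])
  rid <- if (is.character(record)) NA_character_ else as.character(record$record_id[[1]])
  mentions <- scan_texts(text, matcher, negation_window)[[1]]
  flag <- detect_no_treatment(text, matcher$phrases)
  build_record_class(rid, mentions, flag, mode)
}

build_record_class <- function(record_id, mentions, flag, mode) {
  qual <- mentions[!mentions$negated, , drop = FALSE]
  if (mode == "strict") qual <- qual[!qual$uncertain, , drop = FALSE]
  group <- assign_group(qual, flag, mode)
  rule <- group
  if (group == "unknown" && mode == "strict" &&
      length(unique(qual$canonical)) > 1L) {
    rule <- "multi_agent_unclassified"
  }
  structure(list(record_id = record_id, group = group,
                 rule_fired = rule, mentions = mentions,
                 no_treatment_flag = flag),
            class = "ct_record_class")
}

#' Aggregate record classifications to a patient-level first-line label
#'
#' Among records classified into one of the six drug-defined groups, the
#' earliest-dated record determines the patient's first-line treatment
#' group. If none exists, any no-treatment record yields `no_treatment`;
#' otherwise the patient is `unknown`. Positive drug evidence outranks a
#' no-treatment statement on another record regardless of dates.
#'
#' Date policy: under `"undated-first"` (default) treatment records with
#' a missing date sort before dated ones (date unknown, possibly
#' earliest); `"undated-last"` sorts them after. Exact date ties break by
#' `record_id` lexicographic order, so aggregation is deterministic.
#'
#' @param record_classes List of `ct_record_class`, one per record.
#' @param records Data frame of the same records with `patient_id`,
#'   `record_id`, `record_date` (`Date`, `NA` allowed).
#' @param date_policy `"undated-first"` or `"undated-last"`.
#' @return A list of class `ct_patient_class` with `patient_id`, `group`,
#'   `source_record_id` (`NA` for `unknown`), `n_records`.
#' @export
classify_patient <- function(record_classes, records,
                             date_policy = c("undated-first", "undated-last")) {
  date_policy <- match.arg(date_policy)
  pid <- unique(as.character(records$patient_id))
  if (length(pid) != 1L) {
    stop(sprintf("records must share one patient_id, got: %s",
                 paste(pid, collapse = ", ")), call. = FALSE)
  }
  groups <- vapply(record_classes, `[[`, character(1), "group")
  rids <- vapply(record_classes, function(x) as.character(x$record_id), character(1))
  if (!setequal(rids, as.character(records$record_id))) {
    stop("record_classes and records are not aligned by record_id", call. = FALSE)
  }
  dates <- as.Date(records$record_date)[match(rids, as.character(records$record_id))]
  res <- list(patient_id = pid, group = "unknown",
              source_record_id = NA_character_, n_records = length(rids))
  trt <- which(groups %in% DRUG_GROUPS)
  if (length(trt)) {
    d <- as.numeric(dates[trt])
    d[is.na(d)] <- if (date_policy == "undated-first") -Inf else Inf
    pick <- trt[order(d, rids[trt])][1]
    res$group <- groups[pick]
    res$source_record_id <- rids[pick]
  } else if (any(groups == "no_treatment")) {
    pick <- which(groups == "no_treatment")
    pick <- pick[order(rids[pick])][1]
    res$group <- "no_treatment"
    res$source_record_id <- rids[pick]
  }
  structure(res, class = "ct_patient_class")
}

#' Classify a whole corpus of records to patient-level labels
#'
#' Groups records by `patient_id`, classifies each record, and aggregates
#' per patient. Output is one row per distinct patient, ordered by
#' `patient_id`, and is invariant to the input record order.
#'
#' @param records Data frame with columns `patient_id`, `record_id`
#'   (unique), `record_date` (`Date` or coercible, `NA` allowed), `text`.
#' @param matcher A `ct_matcher`.
#' @inheritParams classify_record
#' @inheritParams classify_patient
#' @param keep_record_level If `TRUE`, attach the per-record label data
#'   frame as attribute `"records"`.
#' @return Data frame with columns `patient_id`, `group`,
#'   `source_record_id`, `n_records`.
#' @export
classify_cohort <- function(records, matcher, mode = c("faithful", "strict"),
                            negation_window = 40L,
                            date_policy = c("undated-first", "undated-last"),
                            keep_record_level = FALSE) {
  mode <- match.arg(mode)
  date_policy <- match.arg(date_policy)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("patient_id", "record_id", "record_date", "text")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop(sprintf("records are missing column(s): %s",
                                 paste(miss, collapse = ", ")), call. = FALSE)
  rid <- as.character(records$record_id)
  if (anyDuplicated(rid)) {
    stop(sprintf("duplicate record_id(s): %s",
                 paste(unique(rid[duplicated(rid)]), collapse = ", ")), call. = FALSE)
  }
  # canonical processing order: by patient then record id, so output does
  # not depend on input row order
  ord <- order(as.character(records$patient_id), rid)
  records <- records[ord, , drop = FALSE]
  texts <- normalize_text(records$text)
  mention_sets <- scan_texts(texts, matcher, negation_window)
  flags <- detect_no_treatment_batch(texts, matcher$phrases)
  rcs <- lapply(seq_len(nrow(records)), function(i) {
    build_record_class(as.character(records$record_id[i]),
                       mention_sets[[i]], flags[i], mode)
  })
  rec_df <- data.frame(
    patient_id = as.character(records$patient_id),
    record_id = as.character(records$record_id),
    group = vapply(rcs, `[[`, character(1), "group"),
    rule_fired = vapply(rcs, `[[`, character(1), "rule_fired"),
    n_mentions = vapply(rcs, function(x) nrow(x$mentions), integer(1)),
    evidence = vapply(rcs, function(x) {
      paste(sprintf("%s%s", x$mentions$canonical,
                    ifelse(x$mentions$negated, "[neg]",
                           ifelse(x$mentions$uncertain, "[unc]", ""))),
            collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE)
  out <- lapply(split(seq_len(nrow(records)), as.character(records$patient_id)),
                function(idx) {
                  pc <- classify_patient(rcs[idx], records[idx, , drop = FALSE],
                                         date_policy)
                  data.frame(patient_id = pc$patient_id, group = pc$group,
                             source_record_id = pc$source_record_id,
                             n_records = pc$n_records, stringsAsFactors = FALSE)
                })
  out <- do.call(rbind, out)
  out <- out[order(out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  if (keep_record_level) attr(out, "records") <- rec_df
  out
}

#' @export
print.ct_record_class <- function(x, ...) {
  cat(sprintf("<record %s> %s (rule: %s), %d mention(s)\n",
              x$record_id, x$group, x$rule_fired, nrow(x$mentions)))
  invisible(x)
}

#' @export
print.ct_patient_class <- function(x, ...) {
  cat(sprintf("<patient %s> %s (source record: %s, %d record(s))\n",
              x$patient_id, x$group, x$source_record_id, x$n_records))
  invisible(x)
}
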