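#' Normalize registry free text
#'
#' Lower-cases, collapses every whitespace run to a single space, and
#' strips leading/trailing whitespace. All character offsets reported by
#' the mention scanner refer to this normalized form. Idempotent.
#'
#' @param raw Character vector (may contain `NA`, treated as empty).
#' @return Character vector of the same length.
#' @export
#' @examples
#' normalize_text("  CARBOplatin\t+ Taxol ")
normalize_text <- function(raw) {
  raw[is.na(raw)] <- ""
  x <- tolower(as.character(raw))
  x <- gsub("\\s+", " ", x, perl = TRUE)
  trimws(x)
}

empty_mentions <- function() {
  data.frame(canonical = character(), drug_class = character(),
             start = integer(), end = integer(),
             negated = logical(), uncertain = logical(),
             matched_variant = character(), stringsAsFactors = FALSE)
}

#' Find drug mentions in one record
#'
#' Scans the normalized text of a record for every surface form in the
#' compiled lexicon. Matches are non-overlapping with longest-match
#' preference (so `"carboplatin"` yields one carboplatin mention, never an
#' additional `"carbo"` abbreviation hit inside it), ordered left to
#' right. Each mention is annotated for negation and uncertainty before
#' being returned.
#'
#' @param record A single-row record data frame (see [read_records()]) or
#'   a list with at least a `text` element; a bare character scalar is
#'   also accepted.
#' @param matcher A `ct_matcher` from [compile_lexicon()].
#' @param negation_window Scope window in characters for
#'   mention-window phrases (default 40).
#' @return A data frame with one row per mention and columns `canonical`,
#'   `drug_class`, `start`, `end` (0-based half-open offsets into the
#'   normalized text), `negated`, `uncertain`, `matched_variant`.
#' @export
#' @examples
#' m <- compile_lexicon(default_lexicon())
#' find_mentions("pt started carboplatin and paclitaxel", m)
find_mentions <- function(record, matcher, negation_window = 40L) {
  stopifnot(inherits(matcher, "ct_matcher"))
  text <- if (is.character(record)) record[1] else record$text[[1]]
  text <- normalize_text(text)
  scan_texts(text, matcher, negation_window)[[1]]
}

# Vectorized core: one regex pass per surface form over all texts, then
# per-text overlap suppression and phrase annotation. `texts` must
# already be normalized.
scan_texts <- function(texts, matcher, negation_window = 40L) {
  n <- length(texts)
  out <- rep(list(empty_mentions()), n)
  if (!n) return(out)
  vt <- matcher$variants
  cand <- list()
  nonblank <- which(nzchar(texts))
  if (length(nonblank)) {
    for (i in seq_len(nrow(vt))) {
      ms <- gregexpr(vt$pattern[i], texts[nonblank], perl = TRUE)
      for (j in seq_along(ms)) {
        st <- ms[[j]]
        if (st[1] == -1L) next
        len <- attr(st, "match.length")
        cand[[length(cand) + 1L]] <- data.frame(
          tid = nonblank[j], vid = i,
          start = as.integer(st) - 1L,
          end = as.integer(st) - 1L + as.integer(len),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cand)) return(out)
  cand <- do.call(rbind, cand)
  # leftmost, then longest (variants are length-sorted so vid breaks ties
  # toward the longer surface form)
  cand <- cand[order(cand$tid, cand$start, cand$vid), , drop = FALSE]
  by_text <- split(seq_len(nrow(cand)), cand$tid)
  for (tkey in names(by_text)) {
    t <- as.integer(tkey)
    rows <- cand[by_text[[tkey]], , drop = FALSE]
    keep <- logical(nrow(rows))
    last_end <- 0L
    for (k in seq_len(nrow(rows))) {
      if (rows$start[k] >= last_end) {
        keep[k] <- TRUE
        last_end <- rows$end[k]
      }
    }
    rows <- rows[keep, , drop = FALSE]
    men <- data.frame(
      canonical = vt$canonical[rows$vid],
      drug_class = vt$drug_class[rows$vid],
      start = rows$start, end = rows$end,
      negated = FALSE, uncertain = FALSE,
      matched_variant = vt$variant[rows$vid],
      stringsAsFactors = FALSE)
    out[[t]] <- annotate_negation(texts[t], men, matcher$phrases, negation_window)
  }
  out
}

#' Annotate mentions with negation and uncertainty flags
#'
#' A forward-scope phrase (e.g. "not a candidate for") flags mentions
#' that begin within `window` characters after the end of the phrase
#' match; a backward-scope phrase (e.g. "... but refused") flags mentions
#' that end within `window` characters before the phrase starts;
#' `direction = "both"` applies either side. Negation and uncertainty are
#' independent flags; neither alters the mention span or canonical name.
#' Scope windows deliberately cross punctuation: registry text is
#' fragmentary and no sentence model is assumed.
#'
#' @param text Normalized record text the mention spans refer to.
#' @param mentions Mention data frame as produced by the scanner.
#' @param phrases List of `ct_phrase` objects (only `mention_window`
#'   scoped ones are used).
#' @param window Scope window in characters (default 40).
#' @return The mention data frame with `negated`/`uncertain` filled in.
#' @export
annotate_negation <- function(text, mentions, phrases, window = 40L) {
  if (!nrow(mentions)) return(mentions)
  stopifnot(all(mentions$start >= 0L), all(mentions$end <= nchar(text)),
            all(mentions$start < mentions$end))
  win <- lapply(phrases, function(p) {
    if (p$scope != "mention_window") return(NULL)
    m <- gregexpr(p$pattern, text, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(kind = p$kind, direction = p$direction,
               start = as.integer(m) - 1L,
               end = as.integer(m) - 1L + attr(m, "match.length"),
               stringsAsFactors = FALSE)
  })
  win <- do.call(rbind, win)
  if (is.null(win) || !nrow(win)) return(mentions)
  for (i in seq_len(nrow(mentions))) {
    ms <- mentions$start[i]; me <- mentions$end[i]
    fwd <- win$direction %in% c("forward", "both") &
      win$end <= ms & ms - win$end <= window
    bwd <- win$direction %in% c("backward", "both") &
      win$start >= me & win$start - me <= window
    hit <- win$kind[fwd | bwd]
    if ("negation" %in% hit) mentions$negated[i] <- TRUE
    if ("uncertainty" %in% hit) mentions$uncertain[i] <- TRUE
  }
  mentions
}

#' Detect an explicit whole-record no-treatment statement
#'
#' True when any `no_treatment` phrase (e.g. "patient refused treatment",
#' "opted for hospice instead of treatment", "no treatment given")
#' matches the normalized record text.
#'
#' @param text Raw or normalized record text (scalar).
#' @param phrases List of `ct_phrase` objects; non-`no_treatment` kinds
#'   are ignored.
#' @return Logical scalar.
#' @export
detect_no_treatment <- function(text, phrases) {
  detect_no_treatment_batch(normalize_text(text), phrases)[1]
}

# vectorized over texts (must be normalized): one grepl pass per phrase
detect_no_treatment_batch <- function(texts, phrases) {
  hit <- rep(FALSE, length(texts))
  todo <- nzchar(texts)
  for (p in phrases) {
    if (p$kind != "no_treatment") next
    if (!any(todo)) break
    m <- grepl(p$pattern, texts[todo], perl = TRUE)
    hit[todo][m] <- TRUE
    todo[todo] <- !m
  }
  hit
}
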