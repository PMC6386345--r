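#' @keywords internal
"_PACKAGE"

DRUG_CLASSES <- c("platinum", "pemetrexed", "bevacizumab", "tki", "other_chemo")
PHRASE_KINDS <- c("negation", "uncertainty", "no_treatment")
PHRASE_SCOPES <- c("mention_window", "whole_record")
PHRASE_DIRECTIONS <- c("forward", "backward", "both")

#' Construct a drug term
#'
#' A drug term is one searchable vocabulary entry: a canonical (generic)
#' drug name, the drug class it belongs to, and any surface variants
#' (brand names, abbreviations, curated misspellings) that should map back
#' to the canonical name. The canonical name is always searchable itself.
#'
#' @param canonical Lower-case generic drug name (scalar character).
#' @param drug_class One of `"platinum"`, `"pemetrexed"`, `"bevacizumab"`,
#'   `"tki"`, `"other_chemo"`.
#' @param variants Character vector of additional surface forms (may be
#'   empty). Stored lower-case.
#' @param match_as_word If `TRUE` (default) every variant is matched with
#'   word-boundary assertions, so an abbreviation like `"carbo"` does not
#'   fire inside `"carbohydrate"`.
#' @return A list of class `ct_drug_term`.
#' @export
#' @examples
#' drug_term("erlotinib", "tki", variants = c("tarceva", "erlotnib"))
drug_term <- function(canonical, drug_class, variants = character(), match_as_word = TRUE) {
  canonical <- tolower(trimws(as.character(canonical)))
  if (length(canonical) != 1L || !nzchar(canonical)) {
    stop("`canonical` must be a single non-empty string", call. = FALSE)
  }
  drug_class <- match.arg(drug_class, DRUG_CLASSES)
  variants <- tolower(trimws(as.character(variants)))
  variants <- variants[nzchar(variants)]
  if (length(variants) && any(!nzchar(variants))) {
    stop("variants must be non-empty strings", call. = FALSE)
  }
  variants <- setdiff(unique(variants), canonical)
  structure(
    list(canonical = canonical, drug_class = drug_class,
         variants = variants, match_as_word = isTRUE(match_as_word)),
    class = "ct_drug_term"
  )
}

#' Construct a phrase pattern
#'
#' Phrase patterns drive negation, uncertainty, and no-treatment
#' detection. `negation` and `uncertainty` phrases act within a character
#' window around a drug mention; `no_treatment` phrases are matched
#' against the whole record.
#'
#' @param kind One of `"negation"`, `"uncertainty"`, `"no_treatment"`.
#' @param pattern A Perl-compatible regular expression (matched
#'   case-insensitively against normalized text).
#' @param scope `"mention_window"` or `"whole_record"`. `no_treatment`
#'   phrases must use `"whole_record"`.
#' @param direction For window-scoped phrases, which side of the phrase
#'   the affected mention lies on: `"forward"` (phrase precedes the
#'   mention, e.g. "not a candidate for ..."), `"backward"` (phrase
#'   follows it, e.g. "... but refused"), or `"both"`.
#' @return A list of class `ct_phrase`.
#' @export
phrase_pattern <- function(kind, pattern, scope = NULL, direction = "forward") {
  kind <- match.arg(kind, PHRASE_KINDS)
  if (is.null(scope)) {
    scope <- if (kind == "no_treatment") "whole_record" else "mention_window"
  }
  scope <- match.arg(scope, PHRASE_SCOPES)
  direction <- match.arg(direction, PHRASE_DIRECTIONS)
  if (kind == "no_treatment" && scope != "whole_record") {
    stop("no_treatment phrases must have scope = 'whole_record'", call. = FALSE)
  }
  pattern <- as.character(pattern)
  if (length(pattern) != 1L || !nzchar(pattern)) {
    stop("`pattern` must be a single non-empty string", call. = FALSE)
  }
  ok <- tryCatch({ grepl(pattern, "", perl = TRUE); TRUE }, error = function(e) FALSE)
  if (!ok) stop(sprintf("phrase pattern does not compile: '%s'", pattern), call. = FALSE)
  structure(list(kind = kind, pattern = pattern, scope = scope, direction = direction),
            class = "ct_phrase")
}

#' Construct and validate a lexicon
#'
#' @param terms List of [drug_term()] objects.
#' @param phrases List of [phrase_pattern()] objects.
#' @param version Free-form version string recorded in run logs.
#' @return A list of class `ct_lexicon`.
#' @export
lexicon <- function(terms, phrases = list(), version = "custom") {
  if (!length(terms)) stop("a lexicon needs at least one drug term", call. = FALSE)
  stopifnot(all(vapply(terms, inherits, logical(1), "ct_drug_term")),
            all(vapply(phrases, inherits, logical(1), "ct_phrase")))
  lex <- structure(list(terms = terms, phrases = phrases,
                        version = as.character(version)),
                   class = "ct_lexicon")
  validate_lexicon(lex)
  lex
}

validate_lexicon <- function(lex) {
  canon <- vapply(lex$terms, `[[`, character(1), "canonical")
  if (anyDuplicated(canon)) {
    stop(sprintf("duplicate canonical name(s): %s",
                 paste(unique(canon[duplicated(canon)]), collapse = ", ")),
         call. = FALSE)
  }
  # variant collision: one surface form must map to exactly one canonical
  vt <- variant_table(lex)
  dup <- vt$variant[duplicated(vt$variant)]
  if (length(dup)) {
    bad <- unique(dup)[1]
    owners <- unique(vt$canonical[vt$variant == bad])
    stop(sprintf("variant '%s' maps to multiple canonicals: %s",
                 bad, paste(owners, collapse = ", ")),
         call. = FALSE)
  }
  invisible(lex)
}

# one row per searchable surface form (canonical included)
variant_table <- function(lex) {
  rows <- lapply(lex$terms, function(tm) {
    v <- c(tm$canonical, tm$variants)
    data.frame(variant = v, canonical = tm$canonical,
               drug_class = tm$drug_class, match_as_word = tm$match_as_word,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Load a lexicon from delimited text files
#'
#' The terms file is comma- or tab-delimited with header
#' `canonical,drug_class,variants,match_as_word`; `variants` is
#' pipe-separated and may be empty; `match_as_word` is `true`/`false`.
#' The optional phrase file has header `kind,pattern,scope,direction`
#' (`direction` may be omitted and defaults to `forward`). All surface
#' forms are stored lower-case. Variant collisions (one surface form
#' mapped to two canonicals) are a load-time error.
#'
#' @param path Path to the terms file.
#' @param phrase_path Optional path to the phrase file.
#' @param version Version string; defaults to the terms file name.
#' @return A validated `ct_lexicon`.
#' @seealso [write_lexicon()], [default_lexicon()]
#' @export
load_lexicon <- function(path, phrase_path = NULL, version = basename(path)) {
  if (!file.exists(path)) stop(sprintf("lexicon file not found: %s", path), call. = FALSE)
  df <- read_delimited(path)
  if (!nrow(df)) stop(sprintf("lexicon file is empty: %s", path), call. = FALSE)
  need <- c("canonical", "drug_class", "variants", "match_as_word")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("lexicon file %s is missing column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  terms <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    terms[[i]] <- tryCatch(
      drug_term(
        canonical = df$canonical[i],
        drug_class = df$drug_class[i],
        variants = strsplit(df$variants[i], "|", fixed = TRUE)[[1]],
        match_as_word = parse_bool(df$match_as_word[i])
      ),
      error = function(e) {
        stop(sprintf("malformed lexicon row at line %d of %s: %s",
                     i + 1L, path, conditionMessage(e)), call. = FALSE)
      })
  }
  phrases <- list()
  if (!is.null(phrase_path)) {
    phrases <- load_phrases(phrase_path)
  }
  lexicon(terms, phrases, version = version)
}

load_phrases <- function(path) {
  if (!file.exists(path)) stop(sprintf("phrase file not found: %s", path), call. = FALSE)
  df <- read_delimited(path)
  need <- c("kind", "pattern", "scope")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("phrase file %s is missing column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (is.null(df$direction)) df$direction <- "forward"
  df$direction[is.na(df$direction) | !nzchar(df$direction)] <- "forward"
  lapply(seq_len(nrow(df)), function(i) {
    tryCatch(
      phrase_pattern(df$kind[i], df$pattern[i], df$scope[i], df$direction[i]),
      error = function(e) {
        stop(sprintf("malformed phrase row at line %d of %s: %s",
                     i + 1L, path, conditionMessage(e)), call. = FALSE)
      })
  })
}

#' Write a lexicon back to delimited files
#'
#' Inverse of [load_lexicon()]: `load_lexicon(write_lexicon(lex, ...))`
#' reproduces an identical lexicon.
#'
#' @param lex A `ct_lexicon`.
#' @param path Terms file path to write.
#' @param phrase_path Optional phrase file path.
#' @return Invisibly, `path`.
#' @export
write_lexicon <- function(lex, path, phrase_path = NULL) {
  stopifnot(inherits(lex, "ct_lexicon"))
  df <- data.frame(
    canonical = vapply(lex$terms, `[[`, character(1), "canonical"),
    drug_class = vapply(lex$terms, `[[`, character(1), "drug_class"),
    variants = vapply(lex$terms, function(tm) paste(tm$variants, collapse = "|"), character(1)),
    match_as_word = tolower(vapply(lex$terms, function(tm) tm$match_as_word, logical(1))),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  if (!is.null(phrase_path)) {
    pf <- data.frame(
      kind = vapply(lex$phrases, `[[`, character(1), "kind"),
      pattern = vapply(lex$phrases, `[[`, character(1), "pattern"),
      scope = vapply(lex$phrases, `[[`, character(1), "scope"),
      direction = vapply(lex$phrases, `[[`, character(1), "direction"),
      stringsAsFactors = FALSE
    )
    utils::write.csv(pf, phrase_path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' The packaged default lexicon
#'
#' An era-appropriate (2012-2014, stage IV NSCLC) drug vocabulary with
#' brand names, common abbreviations and curated misspellings, plus
#' default negation / uncertainty / no-treatment phrase lists. The
#' supplementary search-string list of the original registry study is not
#' public, so this vocabulary is a documented reconstruction from the
#' treatment-group definitions; every term and phrase is replaceable via
#' [load_lexicon()].
#'
#' @return A validated `ct_lexicon`.
#' @export
#' @examples
#' lex <- default_lexicon()
#' table(vapply(lex$terms, `[[`, character(1), "drug_class"))
default_lexicon <- function() {
  load_lexicon(
    system.file("extdata", "default_lexicon.csv", package = "chemotext", mustWork = TRUE),
    system.file("extdata", "default_phrases.csv", package = "chemotext", mustWork = TRUE),
    version = "chemotext-default-1"
  )
}

#' Compile a lexicon into a matcher
#'
#' Every surface form becomes a case-insensitive Perl regular expression;
#' word-boundary assertions are added when the term requests them, spaces
#' inside multi-word variants match any whitespace run, and hyphens match
#' an optional hyphen/space (so "nab-paclitaxel" also matches
#' "nab paclitaxel" and "nabpaclitaxel"). At scan time longer variants
#' take precedence over shorter ones and a character position belongs to
#' at most one mention.
#'
#' @param lex A validated `ct_lexicon`.
#' @return An opaque matcher object of class `ct_matcher`.
#' @export
compile_lexicon <- function(lex) {
  stopifnot(inherits(lex, "ct_lexicon"))
  validate_lexicon(lex)
  vt <- variant_table(lex)
  vt$pattern <- vapply(seq_len(nrow(vt)), function(i) {
    variant_regex(vt$variant[i], vt$match_as_word[i])
  }, character(1))
  for (i in seq_len(nrow(vt))) {
    ok <- tryCatch({ grepl(vt$pattern[i], "", perl = TRUE); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop(sprintf("variant does not compile to a valid pattern: '%s'",
                          vt$variant[i]), call. = FALSE)
  }
  # longest surface form first: longest-match preference at equal start
  vt <- vt[order(-nchar(vt$variant), vt$variant), , drop = FALSE]
  rownames(vt) <- NULL
  structure(list(variants = vt, phrases = lex$phrases, version = lex$version),
            class = "ct_matcher")
}

variant_regex <- function(variant, match_as_word) {
  esc <- gsub("([.\\\\+*?\\[\\]^$(){}=!<>|:#-])", "\\\\\\1", variant, perl = TRUE)
  esc <- gsub(" +", "\\\\s+", esc)
  esc <- gsub("\\\\-", "[-\\\\s]?", esc)   # hyphen: optional hyphen or space
  if (match_as_word) esc <- paste0("\\b", esc, "\\b") else esc
}

#' @export
print.ct_lexicon <- function(x, ...) {
  cls <- table(factor(vapply(x$terms, `[[`, character(1), "drug_class"),
                      levels = DRUG_CLASSES))
  cat(sprintf("<ct_lexicon '%s'> %d terms, %d phrases\n",
              x$version, length(x$terms), length(x$phrases)))
  cat("  terms per class:", paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.ct_matcher <- function(x, ...) {
  cat(sprintf("<ct_matcher '%s'> %d surface forms, %d phrase patterns\n",
              x$version, nrow(x$variants), length(x$phrases)))
  invisible(x)
}

# ---- small shared helpers ----

read_delimited <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    colClasses = "character", stringsAsFactors = FALSE,
                    comment.char = "", na.strings = character(),
                    fill = FALSE, strip.white = FALSE, encoding = "UTF-8")
}

parse_bool <- function(x) {
  x <- tolower(trimws(x))
  if (x %in% c("true", "t", "1", "yes")) return(TRUE)
  if (x %in% c("false", "f", "0", "no")) return(FALSE)
  stop(sprintf("cannot parse '%s' as logical", x), call. = FALSE)
}
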