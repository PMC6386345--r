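# Shared fixtures and independent reference implementations used as
# oracles. Everything is built in code; nothing is read from disk except
# files the tests themselves write to tempdir().

toy_lexicon <- function() {
  lexicon(
    terms = list(
      drug_term("carboplatin", "platinum", c("carbo", "paraplatin")),
      drug_term("cisplatin", "platinum"),
      drug_term("pemetrexed", "pemetrexed", "alimta"),
      drug_term("bevacizumab", "bevacizumab", "avastin"),
      drug_term("erlotinib", "tki", c("tarceva", "erlotnib")),
      drug_term("paclitaxel", "other_chemo", "taxol"),
      drug_term("gemcitabine", "other_chemo", "gemzar")
    ),
    phrases = list(
      phrase_pattern("negation", "not a candidate for", "mention_window", "forward"),
      phrase_pattern("negation", "but refused", "mention_window", "backward"),
      phrase_pattern("uncertainty", "unknown if given", "mention_window", "both"),
      phrase_pattern("no_treatment", "no treatment given"),
      phrase_pattern("no_treatment", "\\bhospice\\b")
    ),
    version = "toy-1")
}

toy_matcher <- function() compile_lexicon(toy_lexicon())

make_records <- function(texts, patient_id = "P1", dates = NULL) {
  n <- length(texts)
  data.frame(
    patient_id = rep_len(patient_id, n),
    record_id = sprintf("%s-R%d", rep_len(patient_id, n), seq_len(n)),
    record_date = if (is.null(dates)) as.Date(rep(NA, n)) else as.Date(dates),
    text = texts, stringsAsFactors = FALSE)
}

fake_mentions <- function(canonicals, classes) {
  k <- length(canonicals)
  data.frame(canonical = as.character(canonicals),
             drug_class = as.character(classes),
             start = seq_len(k) * 20L, end = seq_len(k) * 20L + 8L,
             negated = rep(FALSE, k), uncertain = rep(FALSE, k),
             matched_variant = as.character(canonicals),
             stringsAsFactors = FALSE)
}

# Independent brute-force of the sequential-elimination search order: a
# record is run through the six group searches in the published order,
# then the no-treatment search, then falls through to unknown. Written
# from the ordered rules directly, not from assign_group.
reference_search_order <- function(classes, canonicals, flag) {
  has <- function(cl) cl %in% classes
  if (has("tki")) return("tki")
  if (has("pemetrexed") && has("bevacizumab")) return("pem_bev")
  if (has("pemetrexed")) return("pemetrexed_based")
  if (has("bevacizumab")) return("bevacizumab_based")
  if (has("platinum") && any(classes == "other_chemo")) return("platinum_doublet")
  if (length(canonicals) >= 1) return("single_agent")
  if (flag) return("no_treatment")
  "unknown"
}

# Reference kappa from expanded per-patient label vectors: cross-tabulate
# the two raters and apply the chance-corrected agreement definition.
reference_kappa_from_vectors <- function(alg, gold) {
  tab <- table(alg, gold)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}

expand_table_to_vectors <- function(tp, fp, fn, tn) {
  alg <- c(rep("yes", tp), rep("yes", fp), rep("no", fn), rep("no", tn))
  gold <- c(rep("yes", tp), rep("no", fp), rep("yes", fn), rep("no", tn))
  list(alg = factor(alg, c("yes", "no")), gold = factor(gold, c("yes", "no")))
}

# Printed validation counts for the 17,310-patient registry cohort
# (algorithm vs manual review, one-vs-rest per group).
published_counts <- function() {
  read.csv(system.file("extdata", "ccr_table1_counts.csv",
                       package = "chemotext"), stringsAsFactors = FALSE)
}
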