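# Drug pools the generator draws from, keyed so each gold group renders
# text whose noise-free classification is that group.
GEN_PLATINUM <- c("cisplatin", "carboplatin")
GEN_PEM <- "pemetrexed"
GEN_BEV <- "bevacizumab"
GEN_TKI <- c("erlotinib", "gefitinib", "afatinib", "crizotinib")
GEN_OTHER <- c("paclitaxel", "docetaxel", "gemcitabine", "vinorelbine",
               "etoposide", "nab-paclitaxel", "irinotecan")
GEN_SINGLE <- c(GEN_PLATINUM, GEN_OTHER)   # drugs whose solo label is single_agent

NO_TREATMENT_TEMPLATES <- c(
  "patient refused treatment",
  "patient opted for hospice instead of treatment",
  "no treatment given. family declined.",
  "patient died before any treatment given",
  "comfort care only, no chemotherapy planned",
  "best supportive care; no systemic therapy")

NONINFORMATIVE_TEMPLATES <- c(
  "", "", "see notes", "follow up pending", "medical oncology consult placed",
  "records requested from outside facility")

# drugs used by the uncertainty noise channel, with the group their
# unqualified mention maps to (used by expected_confusion)
UNCERTAINTY_DRUGS <- c(erlotinib = "tki", pemetrexed = "pemetrexed_based",
                       carboplatin = "single_agent")

#' Configuration for the synthetic registry-text generator
#'
#' Defaults emulate the validation corpus the package targets: 17,310
#' stage IV NSCLC patients with 24,845 free-text records, a gold-label
#' mix of roughly 32% no systemic treatment and 22% unknown, and the
#' remaining mass over the six drug-defined groups in their observed
#' proportions. `mean_extra_records` (Poisson mean of additional blank
#' records per patient) is set so the mean records-per-patient is about
#' 1.44.
#'
#' Noise channels: `p_misspell`, `p_abbrev`, `p_brand` each
#' independently give the chance that a rendered drug name is replaced
#' by a curated surface variant (misspelling / abbreviation / brand)
#' drawn from the default lexicon; `p_negation_distractor` appends a
#' "not a candidate for <drug>" clause naming a drug from another group;
#' `p_uncertainty` adds, for no-treatment patients, an extra record "<drug>
#' recommended, unknown if given"; `p_blank_extra_record` gives
#' each extra record a chance of being blank rather than boilerplate.
#'
#' @param n_patients Number of patients.
#' @param prevalence Named probability vector over the eight groups
#'   (must sum to 1 within 1e-9).
#' @param mean_extra_records Poisson mean of extra non-informative
#'   records per patient.
#' @param p_misspell,p_abbrev,p_brand,p_negation_distractor,p_uncertainty,p_blank_extra_record
#'   Channel probabilities in `[0, 1]`.
#' @param seed Integer seed; the corpus is a pure function of the config.
#' @return A list of class `ct_sim_config`.
#' @export
simulation_config <- function(n_patients = 1000,
                              prevalence = default_prevalence(),
                              mean_extra_records = 0.44,
                              p_misspell = 0.05,
                              p_abbrev = 0.10,
                              p_brand = 0.15,
                              p_negation_distractor = 0.05,
                              p_uncertainty = 0.0,
                              p_blank_extra_record = 0.8,
                              seed = 1L) {
  prevalence <- prevalence[TREATMENT_GROUPS]
  if (any(is.na(prevalence))) {
    stop("prevalence must name all eight treatment groups", call. = FALSE)
  }
  if (abs(sum(prevalence) - 1) > 1e-9) {
    stop(sprintf("prevalence must sum to 1 (got %.12f)", sum(prevalence)),
         call. = FALSE)
  }
  probs <- c(p_misspell = p_misspell, p_abbrev = p_abbrev, p_brand = p_brand,
             p_negation_distractor = p_negation_distractor,
             p_uncertainty = p_uncertainty,
             p_blank_extra_record = p_blank_extra_record)
  if (any(probs < 0 | probs > 1)) {
    stop("all channel probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (n_patients < 1 || mean_extra_records < 0) {
    stop("n_patients must be >= 1 and mean_extra_records >= 0", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients), prevalence = prevalence,
                 mean_extra_records = mean_extra_records,
                 p_misspell = p_misspell, p_abbrev = p_abbrev, p_brand = p_brand,
                 p_negation_distractor = p_negation_distractor,
                 p_uncertainty = p_uncertainty,
                 p_blank_extra_record = p_blank_extra_record,
                 seed = as.integer(seed)),
            class = "ct_sim_config")
}

#' Default gold-label prevalence for the generator
#'
#' The observed manual-review composition of the 17,310-patient
#' validation cohort: 15.5% platinum doublets, 12.2% pemetrexed-based,
#' 3.1% bevacizumab-based, 3.7% pemetrexed+bevacizumab, 1.9% single
#' agents, 9.9% TKIs, 31.7% no treatment, 22.1% unknown.
#'
#' @return Named numeric vector over the eight groups summing to 1.
#' @export
default_prevalence <- function() {
  counts <- c(tki = 1716, pem_bev = 635, pemetrexed_based = 2114,
              bevacizumab_based = 530, platinum_doublet = 2688,
              single_agent = 325, no_treatment = 5486, unknown = 3817)
  (counts / sum(counts))[TREATMENT_GROUPS]
}

#' Generate a gold-labeled synthetic registry corpus
#'
#' For each patient a gold group is drawn from the configured prevalence
#' and one informative record is rendered from group-consistent phrase
#' templates (drug names drawn per the group definition, e.g. a platinum
#' plus a distinct other chemotherapy drug for platinum doublets), plus
#' zero or more extra non-informative records. Noise channels perturb
#' surface forms and append negated-distractor or uncertainty clauses as
#' described in [simulation_config()]. The generator never uses the
#' classifier; gold labels come from the construction itself. Byte-for-
#' byte reproducible from the config (the global RNG state is restored
#' on exit).
#'
#' @param config A `ct_sim_config`.
#' @return A list of class `ct_corpus`: `records` (data frame
#'   `patient_id`, `record_id`, `record_date`, `text`), `gold` (data
#'   frame `patient_id`, `group`), `config_used`.
#' @export
#' @examples
#' corp <- generate_corpus(simulation_config(n_patients = 5, seed = 42))
#' corp$records$text
generate_corpus <- function(config) {
  stopifnot(inherits(config, "ct_sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  lex <- default_lexicon()
  variants_of <- lapply(lex$terms, `[[`, "variants")
  names(variants_of) <- vapply(lex$terms, `[[`, character(1), "canonical")

  n <- config$n_patients
  width <- max(4L, nchar(as.character(n)))
  pids <- sprintf("P%0*d", width, seq_len(n))
  gold_groups <- sample(TREATMENT_GROUPS, n, replace = TRUE,
                        prob = config$prevalence)
  p_swap <- min(1, config$p_misspell + config$p_abbrev + config$p_brand)

  render_drug <- function(canonical) {
    v <- variants_of[[canonical]]
    if (length(v) && stats::runif(1) < p_swap) sample(v, 1) else canonical
  }

  recs <- vector("list", n)
  for (i in seq_len(n)) {
    g <- gold_groups[i]
    date0 <- as.Date("2012-01-01") + sample.int(1095, 1) - 1L
    text <- render_primary_text(g, render_drug)
    if (g != "unknown" && stats::runif(1) < config$p_negation_distractor) {
      distractor <- sample(distractor_pool(g), 1)
      text <- paste0(text, if (nzchar(text)) ". " else "",
                     "not a candidate for ", render_drug(distractor))
    }
    texts <- text
    if (g == "no_treatment" && stats::runif(1) < config$p_uncertainty) {
      ud <- sample(names(UNCERTAINTY_DRUGS), 1)
      texts <- c(texts, paste0(ud, " recommended, unknown if given"))
    }
    n_extra <- stats::rpois(1, config$mean_extra_records)
    texts <- c(texts, vapply(seq_len(n_extra), function(k) {
      if (stats::runif(1) < config$p_blank_extra_record) ""
      else sample(NONINFORMATIVE_TEMPLATES[nzchar(NONINFORMATIVE_TEMPLATES)], 1)
    }, character(1)))
    dates <- date0 + (seq_along(texts) - 1L) * 30L
    recs[[i]] <- data.frame(
      patient_id = pids[i],
      record_id = sprintf("%s-R%d", pids[i], seq_along(texts)),
      record_date = dates, text = texts, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  structure(list(records = records,
                 gold = data.frame(patient_id = pids, group = gold_groups,
                                   stringsAsFactors = FALSE),
                 config_used = config),
            class = "ct_corpus")
}

render_primary_text <- function(group, render_drug) {
  two_from <- function(pool) sample(pool, 2)
  switch(group,
    tki = sprintf("%s %dmg daily started", render_drug(sample(GEN_TKI, 1)),
                  sample(c(150L, 250L, 40L), 1)),
    pem_bev = {
      extras <- if (stats::runif(1) < 0.5)
        paste0(" and ", render_drug(sample(GEN_PLATINUM, 1))) else ""
      sprintf("%s, %s%s given", render_drug(GEN_PEM), render_drug(GEN_BEV), extras)
    },
    pemetrexed_based = {
      extras <- if (stats::runif(1) < 0.6)
        paste0(" with ", render_drug(sample(GEN_PLATINUM, 1))) else ""
      sprintf("started %s%s", render_drug(GEN_PEM), extras)
    },
    bevacizumab_based = {
      extras <- if (stats::runif(1) < 0.6)
        paste0("/", render_drug(sample(c(GEN_PLATINUM, GEN_OTHER), 1))) else ""
      sprintf("%s%s x%d cycles", render_drug(GEN_BEV), extras, sample(2:6, 1))
    },
    platinum_doublet = {
      sprintf("chemo with %s and %s initiated",
              render_drug(sample(GEN_PLATINUM, 1)),
              render_drug(sample(GEN_OTHER, 1)))
    },
    single_agent = sprintf("%s single agent", render_drug(sample(GEN_SINGLE, 1))),
    no_treatment = sample(NO_TREATMENT_TEMPLATES, 1),
    unknown = sample(NONINFORMATIVE_TEMPLATES, 1))
}

# drugs whose presence (non-negated) would change the label of `group`;
# safe as negated distractors for it
distractor_pool <- function(group) {
  switch(group,
    tki = c(GEN_PEM, GEN_BEV, GEN_PLATINUM),
    pem_bev = GEN_TKI,
    pemetrexed_based = c(GEN_TKI, GEN_BEV),
    bevacizumab_based = c(GEN_TKI, GEN_PEM),
    platinum_doublet = c(GEN_TKI, GEN_PEM, GEN_BEV),
    single_agent = c(GEN_TKI, GEN_PEM, GEN_BEV),
    no_treatment = c(GEN_TKI, GEN_PEM, GEN_BEV, GEN_PLATINUM, GEN_OTHER),
    unknown = character())
}

#' Closed-form confusion probabilities for a generator configuration
#'
#' For the analytically tractable noise subset, returns the per-patient
#' probability `P(predicted = j | gold = i)` the classifier attains on
#' corpora from `config`. Surface-variant swaps, negated distractors and
#' blank extra records leave classification exact (variants are in the
#' lexicon; distractors are negated; blanks are unknown at record level
#' and never override an informative record), so the matrix is the
#' identity except for the uncertainty channel: in `faithful` mode an
#' uncertainty record on a no-treatment patient contributes a
#' non-negated drug mention and moves the patient to that drug's group
#' (uniformly over the channel's drug set); in `strict` mode uncertain
#' mentions are discarded and the matrix is again the identity.
#'
#' @param config A `ct_sim_config`.
#' @param mode `"faithful"` or `"strict"` (must match the mode used to
#'   classify).
#' @return An 8x8 row-stochastic matrix, rows = gold, columns =
#'   predicted.
#' @export
expected_confusion <- function(config, mode = c("faithful", "strict")) {
  stopifnot(inherits(config, "ct_sim_config"))
  mode <- match.arg(mode)
  m <- diag(length(TREATMENT_GROUPS))
  dimnames(m) <- list(gold = TREATMENT_GROUPS, predicted = TREATMENT_GROUPS)
  q <- config$p_uncertainty
  if (q > 0 && mode == "faithful") {
    targets <- UNCERTAINTY_DRUGS
    m["no_treatment", "no_treatment"] <- 1 - q
    for (tg in targets) {
      m["no_treatment", tg] <- m["no_treatment", tg] + q / length(targets)
    }
  }
  m
}

#' Write a corpus to delimited files
#'
#' @param corpus A `ct_corpus`.
#' @param records_path,gold_path Output CSV paths.
#' @param config_path Optional path for a key-value echo of the config.
#' @return Invisibly, `records_path`.
#' @export
write_corpus <- function(corpus, records_path, gold_path, config_path = NULL) {
  stopifnot(inherits(corpus, "ct_corpus"))
  rec <- corpus$records
  rec$record_date <- format(rec$record_date, "%Y-%m-%d")
  utils::write.csv(rec, records_path, row.names = FALSE, quote = TRUE)
  utils::write.csv(corpus$gold, gold_path, row.names = FALSE, quote = TRUE)
  if (!is.null(config_path)) {
    cfg <- corpus$config_used
    flat <- c(n_patients = cfg$n_patients,
              stats::setNames(as.vector(cfg$prevalence),
                              paste0("prevalence.", names(cfg$prevalence))),
              mean_extra_records = cfg$mean_extra_records,
              p_misspell = cfg$p_misspell, p_abbrev = cfg$p_abbrev,
              p_brand = cfg$p_brand,
              p_negation_distractor = cfg$p_negation_distractor,
              p_uncertainty = cfg$p_uncertainty,
              p_blank_extra_record = cfg$p_blank_extra_record,
              seed = cfg$seed)
    writeLines(sprintf("%s: %s", names(flat), as.character(flat)), config_path)
  }
  invisible(records_path)
}

#' @export
print.ct_corpus <- function(x, ...) {
  cat(sprintf("<ct_corpus> %d records, %d patients (seed %d)\n",
              nrow(x$records), nrow(x$gold), x$config_used$seed))
  invisible(x)
}
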