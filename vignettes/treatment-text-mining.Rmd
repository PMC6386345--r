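---
title: "Mining first-line systemic treatment from registry free text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining first-line systemic treatment from registry free text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemotext)
```

## The problem

Population-based cancer registries record first-line systemic therapy in
free-text fields: telegraphic fragments written by tumor registrars
("carbo/taxol x4 cycles", "pt not a candidate for tarceva; hospice").
The drug-level detail never reaches the coded fields, so population-level
surveillance of regimen use — who received a platinum doublet, who got a
tyrosine kinase inhibitor (TKI), who was never treated — requires either
slow manual abstraction or automated text mining. `chemotext` implements
a rule-based mining pipeline for stage IV non-small cell lung cancer
(NSCLC) in the 2012–2014 treatment era, together with the validation
machinery (agreement, kappa, diagnostic accuracy) used to compare an
algorithm against a manual-review gold standard, and a synthetic corpus
generator so that the whole system can be exercised without access to
confidential registry data.

## The classification model

Each patient is assigned exactly one of eight labels. Six are
drug-defined groups aligned with treatment guidelines of that era:

1. **tki** — any tyrosine kinase inhibitor (erlotinib, gefitinib,
   afatinib, crizotinib);
2. **pem_bev** — pemetrexed and bevacizumab together (with or without a
   platinum);
3. **pemetrexed_based** — pemetrexed alone or with platinum/other
   chemotherapy;
4. **bevacizumab_based** — bevacizumab alone or with platinum/other
   chemotherapy (excluding pemetrexed);
5. **platinum_doublet** — a platinum agent (cisplatin/carboplatin) plus a
   distinct other chemotherapy drug, excluding pemetrexed and
   bevacizumab;
6. **single_agent** — one remaining drug (platinum or non-platinum).

Two further labels complete the partition: **no_treatment** (an explicit
statement that none was given — refusal, hospice, death before
treatment) and **unknown** (blank or non-informative text).

The original registry algorithm searches the corpus one group at a time
in the order above — most specific drug sets first — removing matched
records before the next search. `chemotext` re-expresses this
*sequential elimination* as a per-record precedence over the drug
classes present among non-negated mentions. The two formulations are
equivalent for record labels: a record matched at stage *k* is exactly a
record whose evidence satisfies rule *k* and none of the rules before
it. The precedence form is easier to audit — each record carries a
`rule_fired` value — and is what `assign_group()` implements. The test
suite checks the equivalence exhaustively against a brute-force
implementation of the staged search over all 2^5 class-presence
combinations.

Distinctness is by canonical drug name: "carboplatin ... carboplatin" is
one agent, not a doublet. Multi-drug combinations with no platinum,
pemetrexed, bevacizumab, or TKI (e.g. gemcitabine + docetaxel) are not
one of the six defined groups; the default `faithful` mode lets the
final broad drug search absorb them as `single_agent`, which mirrors the
published algorithm's behaviour (and is consistent with the low positive
predictive value reported for that group); `strict` mode sends them to
`unknown` instead.

## Matching: lexicon, negation, uncertainty

All matching runs over normalized text (lower-cased, whitespace
collapsed) with Perl-compatible regular expressions. The shipped lexicon
is a reconstruction of an era-appropriate NSCLC vocabulary — the exact
search-string list used in the original registry study is not public —
with brand names (Tarceva, Alimta, Avastin, ...), abbreviations (carbo,
CDDP, VP-16), and curated misspellings as explicit variants of each
canonical drug. Misspellings are enumerated, not fuzzy-matched: an
edit-distance matcher would change the error characteristics of the
method, whereas a curated list keeps them inspectable. Every term and
phrase is replaceable through the delimited lexicon file format
(`load_lexicon()`).

Three matching rules matter:

* **Word boundaries** (default on) keep "carbo" from firing inside
  "carbohydrate". Hyphens in variants also match a space or nothing, so
  "nab-paclitaxel" covers "nab paclitaxel".
* **Longest match wins** and a character position belongs to at most one
  mention, so "carboplatin" never double-counts as "carbo" plus a tail.
* **Negation and uncertainty** are window-based. A forward phrase ("not
  a candidate for", "expired before receiving") flags mentions that
  start within 40 characters after it; a backward phrase ("... but
  refused") flags mentions that end within 40 characters before it;
  "refused"/"declined" work in both directions. The phrase file carries
  a `direction` column for this, because example phrases alone do not
  determine which side of a drug name they act on. The 40-character
  default is configurable (`negation_window`); it is wide enough for the
  connective tissue of registry fragments ("not a candidate for further
  erlotinib") and narrow enough not to leak across unrelated clauses in
  longer fields. Sentence boundaries are deliberately *not* modelled:
  registry text is fragmentary, and an unspecified sentence segmenter
  would be a larger source of silent behaviour than a fixed window. The
  window crossing punctuation is a documented limitation.

Uncertainty phrases ("unknown if given") set an independent flag. In
`faithful` mode uncertain mentions still count as treatment evidence —
matching the false-positive behaviour reported for the original
algorithm — while `strict` mode discards them.

A record with any surviving (non-negated) drug mention can never be
`no_treatment`: the no-treatment search runs after all six drug
searches, so positive evidence always wins at record level.

## Patient-level aggregation

Patients often have several records. Among records classified into the
six drug groups, the earliest `record_date` determines the first-line
label. Three policies had to be fixed where the underlying procedure is
described only as "dates were used":

* **Undated records** sort first by default ("date unknown, possibly
  earliest"); `date_policy = "undated-last"` reverses this.
* **Exact ties** break by `record_id` lexicographic order, so results
  are reproducible.
* A patient with both a treatment-group record and a no-treatment record
  is labelled by the treatment record regardless of dates: a drug
  mention is direct positive evidence, a refusal note on another report
  is not evidence the drug was never given elsewhere.

Dates inside the text itself are not parsed; only the structured date
field orders records.

## Evaluation statistics

Validation is patient-level and one-vs-rest: for each group, algorithm
and gold labels are dichotomized and cross-tabulated into a 2×2 table
(`tp` = both yes, `fp` = algorithm only, `fn` = gold only, `tn` =
neither). From each table the package computes percent agreement
`(tp+tn)/n`, Cohen's kappa `(po − pe)/(1 − pe)` with `pe` from the
marginals, sensitivity, specificity, PPV, NPV, and false-positive /
false-negative / total-error counts.

Confidence intervals: the original report does not state its CI method,
and the printed intervals are too coarse to identify one. The package
defaults to Wilson score intervals for proportions (well-behaved near 0
and 1, where several of these metrics live) with Wald and
Clopper–Pearson as options, and the large-sample standard error
`sqrt(po(1−po)/n)/(1−pe)` for kappa. Because the method could not be
pinned down, the package's exactness claims are confined to point
estimates.

Display rounding is half-up (one decimal for percentages, two for
kappa), matching how such tables are conventionally printed; R's
`round()` would round half to even.

Feeding the published 17,310-patient contingency counts (shipped in
`inst/extdata/ccr_table1_counts.csv`) through `evaluate_counts()`
reproduces the published agreement, kappa, accuracy, and error values at
printed precision, with four printed cells excepted: the TKI kappa
(prints 0.88, counts give 0.87), platinum-doublet sensitivity (prints
90.0, counts give 2442/2688 = 90.8), pemetrexed-based specificity
(prints 98.9, counts give 99.0) and unknown-group NPV (prints 92.9,
counts give 93.0). These look like transcription or truncation slips in
the printed table — each conflicts with its own column's counts — so the
package asserts the count-consistent values.

## The synthetic corpus generator

`generate_corpus()` renders registry-style records from group-consistent
templates with known gold labels. Defaults mirror the published cohort
composition: prevalences from the manual-review margins (31.7% no
treatment, 22.1% unknown, 15.5% platinum doublets, ...), and a Poisson
number of extra non-informative records per patient with mean 0.44, so
the mean records-per-patient is ≈1.44 (the published corpus had 24,845
records for 17,310 patients).

Noise channels and their intended analytic behaviour:

* surface swaps (`p_brand`, `p_abbrev`, `p_misspell`) replace a canonical
  name by a lexicon variant — recognized by construction, so patient
  labels are unaffected;
* `p_negation_distractor` appends "not a candidate for X" with X from a
  group that would otherwise change the label — the negation annotator
  must remove it;
* `p_uncertainty` gives no-treatment patients an extra record "X
  recommended, unknown if given" — in `faithful` mode this moves the
  patient to X's group, in `strict` mode it does not;
* `p_blank_extra_record` controls whether extra records are blank or
  boilerplate — blank records are `unknown` at record level and never
  override an informative record.

`expected_confusion()` returns the closed-form per-patient confusion
matrix implied by this design: the identity, except that the
no-treatment row loses mass `p_uncertainty` uniformly to the uncertainty
channel's drug set in `faithful` mode. Monte-Carlo tests check the
empirical confusion of generate → classify against this closed form at
5,000 patients over three seeds, with tolerances set at roughly four
binomial standard errors for the stratum sizes involved; the zero-noise
and saturated-distractor round trips use 1,000 patients. These sizes
make the sampling error small relative to the effects tested while
keeping the full suite fast.

What the generator does **not** emulate — and therefore what perfect
synthetic recovery does and does not show: real registry text has
unbounded spelling variation (the lexicon is closed), multi-treatment
histories across facilities with conflicting dates, treatment options
*discussed* but not given without any negation cue, and drugs shared
between groups in ambiguous phrasings. Those are exactly the error
sources behind the published false-positive and false-negative rates, so
synthetic 100% recovery validates the machinery (matching, negation
scoping, precedence, aggregation, evaluation), not the field accuracy of
any particular lexicon. Published accuracy on real registry data is
reproduced in this package only through the printed contingency counts.

## Numerical and degenerate-input choices

* Metric denominators of zero (e.g. specificity when a group is
  universal) raise a named error rather than returning `NaN`; kappa with
  degenerate marginals (`pe = 1`) likewise.
* The generator restores the caller's RNG state, so corpus generation is
  reproducible without side effects on the session.
* `classify_cohort()` canonicalizes processing order by patient and
  record id, making output invariant to input row order; repeated runs
  are byte-identical.
* Empty text is legal everywhere and means "non-informative", never an
  error.

## Limitations

* The shipped lexicon is a documented reconstruction, not the original
  registry search-string list; users validating against their own
  registry should expect to iterate on it (sample, review matched and
  unmatched records, extend variants and phrases, repeat).
* Immune checkpoint inhibitors are out of vocabulary by design: they
  postdate the 2012–2014 group definitions.
* Negation scope is a fixed character window without sentence or
  syntactic structure; long coordinated clauses can defeat it.
* Dose, route, and cycle counts are not extracted.
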