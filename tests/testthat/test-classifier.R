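test_that("assign_group follows the published precedence on worked cases", {
  m3 <- fake_mentions(c("pemetrexed", "bevacizumab", "carboplatin"),
                      c("pemetrexed", "bevacizumab", "platinum"))
  expect_equal(assign_group(m3, FALSE), "pem_bev")
  expect_equal(assign_group(fake_mentions(character(), character()), FALSE), "unknown")
  expect_equal(assign_group(fake_mentions(c("cisplatin", "gemcitabine"),
                                          c("platinum", "other_chemo")), FALSE),
               "platinum_doublet")
  expect_equal(assign_group(fake_mentions(c("erlotinib", "carboplatin"),
                                          c("tki", "platinum")), FALSE), "tki")
  # distinctness is by canonical name: repeated carboplatin is one agent
  expect_equal(assign_group(fake_mentions(c("carboplatin", "carboplatin"),
                                          c("platinum", "platinum")), FALSE),
               "single_agent")
  expect_equal(assign_group(fake_mentions(character(), character()), TRUE),
               "no_treatment")
})

test_that("assign_group matches a brute-force reference over all class combinations", {
  classes <- c("platinum", "pemetrexed", "bevacizumab", "tki", "other_chemo")
  for (mask in 0:(2^5 - 1)) {
    present <- classes[bitwAnd(mask, 2^(0:4)) > 0]
    canon <- if (length(present)) paste0("drug_", present) else character(0)
    mentions <- fake_mentions(canon, present)
    for (flag in c(FALSE, TRUE)) {
      expect_equal(assign_group(mentions, flag),
                   reference_search_order(present, canon, flag),
                   info = sprintf("classes={%s} flag=%s",
                                  paste(present, collapse = ","), flag))
    }
  }
})

test_that("pem+bev evidence is never absorbed by a lower-precedence group", {
  classes <- c("platinum", "pemetrexed", "bevacizumab", "tki", "other_chemo")
  for (mask in 0:(2^5 - 1)) {
    present <- classes[bitwAnd(mask, 2^(0:4)) > 0]
    if (!all(c("pemetrexed", "bevacizumab") %in% present)) next
    g <- assign_group(fake_mentions(paste0("d_", present), present), FALSE)
    expect_false(g %in% c("platinum_doublet", "pemetrexed_based",
                          "bevacizumab_based", "single_agent"))
  }
})

test_that("strict mode sends multi-drug non-platinum combinations to unknown", {
  men <- fake_mentions(c("gemcitabine", "paclitaxel"),
                       c("other_chemo", "other_chemo"))
  expect_equal(assign_group(men, FALSE, mode = "faithful"), "single_agent")
  expect_equal(assign_group(men, FALSE, mode = "strict"), "unknown")
})

test_that("classify_record runs the full pipeline with audit trail", {
  m <- compile_lexicon(default_lexicon())
  r1 <- classify_record(list(record_id = "r1",
                             text = "not a candidate for erlotinib; hospice"), m)
  expect_equal(r1$group, "no_treatment")
  expect_true(r1$mentions$negated)
  r2 <- classify_record(list(record_id = "r2", text = ""), m)
  expect_equal(r2$group, "unknown")
  r3 <- classify_record(list(record_id = "r3",
                             text = "alimta + avastin + carbo started"), m)
  expect_equal(r3$group, "pem_bev")
  expect_equal(r3$rule_fired, "pem_bev")
  # a record with live drug evidence can never be no_treatment
  r4 <- classify_record(list(record_id = "r4",
                             text = "no treatment given initially; later carboplatin and taxol"), m)
  expect_true(r4$no_treatment_flag)
  expect_equal(r4$group, "platinum_doublet")
})

test_that("uncertain mentions count in faithful mode but not in strict mode", {
  m <- compile_lexicon(default_lexicon())
  tx <- "pemetrexed recommended, unknown if given"
  expect_equal(classify_record(list(record_id = "u", text = tx), m,
                               mode = "faithful")$group, "pemetrexed_based")
  expect_equal(classify_record(list(record_id = "u", text = tx), m,
                               mode = "strict")$group, "unknown")
})

test_that("earliest-dated treatment record determines the patient label", {
  m <- toy_matcher()
  recs <- make_records(c("carboplatin and taxol started", "tarceva started"),
                       dates = c("2013-01-05", "2013-03-01"))
  rcs <- lapply(seq_len(nrow(recs)), function(i) classify_record(recs[i, ], m))
  pc <- classify_patient(rcs, recs)
  expect_equal(pc$group, "platinum_doublet")
  expect_equal(pc$source_record_id, "P1-R1")
  # reversed dates flip the winner
  recs$record_date <- as.Date(c("2013-03-01", "2013-01-05"))
  pc2 <- classify_patient(rcs, recs)
  expect_equal(pc2$group, "tki")
})

test_that("no_treatment outranks unknown; treatment outranks no_treatment", {
  m <- toy_matcher()
  recs <- make_records(c("", "no treatment given"))
  rcs <- lapply(seq_len(nrow(recs)), function(i) classify_record(recs[i, ], m))
  expect_equal(classify_patient(rcs, recs)$group, "no_treatment")
  recs2 <- make_records(c("no treatment given", "tarceva started"),
                        dates = c("2012-01-01", "2013-06-01"))
  rcs2 <- lapply(seq_len(nrow(recs2)), function(i) classify_record(recs2[i, ], m))
  expect_equal(classify_patient(rcs2, recs2)$group, "tki")
})

test_that("date policy governs undated treatment records deterministically", {
  m <- toy_matcher()
  recs <- make_records(c("tarceva started", "carboplatin and taxol started"),
                       dates = c(NA, "2013-02-01"))
  rcs <- lapply(seq_len(nrow(recs)), function(i) classify_record(recs[i, ], m))
  expect_equal(classify_patient(rcs, recs, date_policy = "undated-first")$group, "tki")
  expect_equal(classify_patient(rcs, recs, date_policy = "undated-last")$group,
               "platinum_doublet")
  # exact date tie breaks by record_id, so the result is reproducible
  recs$record_date <- as.Date(c("2013-02-01", "2013-02-01"))
  expect_equal(classify_patient(rcs, recs)$source_record_id, "P1-R1")
})

test_that("classify_patient rejects mixed patients and misaligned records", {
  m <- toy_matcher()
  recs <- make_records("tarceva started")
  rcs <- list(classify_record(recs[1, ], m))
  recs_bad <- recs; recs_bad$patient_id <- "P9"
  expect_error(classify_patient(rcs, rbind(recs, recs_bad)), "one patient_id")
})

test_that("classify_cohort yields one row per patient and checks record ids", {
  m <- toy_matcher()
  recs <- rbind(make_records(c("tarceva started", ""), patient_id = "P1"),
                make_records("no treatment given", patient_id = "P2"))
  out <- classify_cohort(recs, m)
  expect_equal(nrow(out), 2)
  expect_equal(out$group, c("tki", "no_treatment"))
  expect_equal(out$n_records, c(2L, 1L))
  dup <- rbind(recs, recs[1, ])
  expect_error(classify_cohort(dup, m), "duplicate record_id")
  blank <- make_records(c("", ""), patient_id = "P3")
  expect_equal(classify_cohort(blank, m)$group, "unknown")
})

test_that("classify_cohort is invariant to input record order", {
  m <- compile_lexicon(default_lexicon())
  corp <- generate_corpus(simulation_config(n_patients = 60, seed = 5))
  out1 <- classify_cohort(corp$records, m)
  set.seed(99)
  shuffled <- corp$records[sample(nrow(corp$records)), ]
  out2 <- classify_cohort(shuffled, m)
  expect_identical(out1, out2)
})

test_that("negating all drug evidence can only move a label to no_treatment/unknown", {
  classes <- c("platinum", "pemetrexed", "bevacizumab", "tki", "other_chemo")
  set.seed(13)
  for (i in 1:30) {
    present <- sample(classes, sample(1:4, 1))
    for (flag in c(FALSE, TRUE)) {
      with_drugs <- assign_group(fake_mentions(paste0("d_", present), present), flag)
      all_negated <- assign_group(fake_mentions(character(), character()), flag)
      expect_true(all_negated %in% c("no_treatment", "unknown"))
      expect_true(with_drugs %in% treatment_groups())
    }
  }
})
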