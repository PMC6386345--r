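test_that("build_contingency dichotomizes correctly and checks patient sets", {
  pred <- data.frame(patient_id = c("A", "B"), group = c("tki", "unknown"))
  gold <- data.frame(patient_id = c("A", "B"), group = c("tki", "tki"))
  t <- build_contingency(pred, gold, "tki")
  expect_equal(unlist(t[c("tp", "fp", "fn", "tn")]),
               c(tp = 1L, fp = 0L, fn = 1L, tn = 0L))
  expect_error(build_contingency(pred, gold[1, , drop = FALSE], "tki"),
               "patient sets differ")
  same <- build_contingency(gold, gold, "tki")
  expect_equal(same$fp + same$fn, 0L)
})

test_that("summed per-group true positives equal exact label agreements", {
  set.seed(301)
  ids <- sprintf("P%03d", 1:100)
  pred <- data.frame(patient_id = ids,
                     group = sample(treatment_groups(), 100, replace = TRUE))
  gold <- data.frame(patient_id = ids,
                     group = sample(treatment_groups(), 100, replace = TRUE))
  tps <- vapply(treatment_groups(),
                function(g) build_contingency(pred, gold, g)$tp, integer(1))
  expect_equal(sum(tps), sum(pred$group == gold$group))
})

test_that("percent agreement reproduces published registry values", {
  expect_equal(round_half_up(100 * percent_agreement(
    contingency_2x2(2442, 90, 246, 14532))$estimate, 1), 98.1)
  expect_equal(round_half_up(100 * percent_agreement(
    contingency_2x2(288, 189, 37, 16796))$estimate, 1), 98.7)
  expect_equal(percent_agreement(contingency_2x2(1, 0, 0, 1))$estimate, 1.0)
})

test_that("kappa reproduces published values and its boundary cases", {
  expect_equal(round_half_up(cohen_kappa(
    contingency_2x2(2442, 90, 246, 14532))$estimate, 2), 0.92)
  expect_equal(round_half_up(cohen_kappa(
    contingency_2x2(288, 189, 37, 16796))$estimate, 2), 0.71)
  expect_equal(round_half_up(cohen_kappa(
    contingency_2x2(4844, 895, 642, 10929))$estimate, 2), 0.80)
  expect_equal(cohen_kappa(contingency_2x2(10, 0, 0, 10))$estimate, 1.0)
  # po = pe by construction: chance-level agreement gives kappa 0
  expect_equal(cohen_kappa(contingency_2x2(1, 1, 1, 1))$estimate, 0)
  expect_error(cohen_kappa(contingency_2x2(5, 0, 0, 0)), "degenerate")
})

test_that("kappa on the table equals kappa from expanded label vectors", {
  set.seed(77)
  for (i in 1:50) {
    cc <- rmultinom(1, size = sample(20:60, 1), prob = c(0.3, 0.2, 0.2, 0.3))[, 1]
    t <- contingency_2x2(cc[1], cc[2], cc[3], cc[4])
    v <- expand_table_to_vectors(cc[1], cc[2], cc[3], cc[4])
    pe_chk <- ((t$tp + t$fp) * (t$tp + t$fn) + (t$fn + t$tn) * (t$fp + t$tn)) / sum(cc)^2
    if (pe_chk >= 1) next
    expect_equal(cohen_kappa(t)$estimate,
                 reference_kappa_from_vectors(v$alg, v$gold), tolerance = 1e-12)
  }
})

test_that("kappa agrees with an independent library implementation", {
  skip_if_not_installed("e1071")
  set.seed(78)
  for (i in 1:20) {
    cc <- rmultinom(1, 50, prob = c(0.4, 0.1, 0.1, 0.4))[, 1]
    if (sum(cc[1:2]) == 0 || sum(cc[3:4]) == 0) next
    tab <- matrix(cc, 2, 2, byrow = TRUE)  # rows algorithm, cols gold
    if (((cc[1]+cc[2])*(cc[1]+cc[3]) + (cc[3]+cc[4])*(cc[2]+cc[4])) / sum(cc)^2 >= 1) next
    expect_equal(cohen_kappa(contingency_2x2(cc[1], cc[2], cc[3], cc[4]))$estimate,
                 e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
  }
})

test_that("accuracy metrics reproduce published values with exact identities", {
  expect_equal(round_half_up(100 * sensitivity(
    contingency_2x2(618, 114, 17, 16561))$estimate, 1), 97.3)
  expect_equal(round_half_up(100 * specificity(
    contingency_2x2(467, 35, 63, 16745))$estimate, 1), 99.8)
  expect_equal(round_half_up(100 * ppv(
    contingency_2x2(288, 189, 37, 16796))$estimate, 1), 60.4)
  expect_error(specificity(contingency_2x2(1, 0, 0, 0)), "specificity")
  set.seed(9)
  for (i in 1:20) {
    cc <- rmultinom(1, 200, prob = rep(0.25, 4))[, 1] + 1L
    t <- contingency_2x2(cc[1], cc[2], cc[3], cc[4])
    expect_equal(sensitivity(t)$estimate * (t$tp + t$fn), t$tp)
    expect_equal(specificity(t)$estimate * (t$tn + t$fp), t$tn)
    expect_equal(ppv(t)$estimate * (t$tp + t$fp), t$tp)
    expect_equal(npv(t)$estimate * (t$tn + t$fn), t$tn)
    # chance-corrected agreement can never exceed raw agreement
    expect_lte(cohen_kappa(t)$estimate, percent_agreement(t)$estimate)
  }
})

test_that("metric confidence intervals bracket the estimate for all methods", {
  set.seed(10)
  for (method in c("wilson", "wald", "exact")) {
    for (i in 1:15) {
      cc <- rmultinom(1, 120, prob = rep(0.25, 4))[, 1] + 1L
      t <- contingency_2x2(cc[1], cc[2], cc[3], cc[4])
      for (f in list(percent_agreement, sensitivity, specificity, ppv, npv)) {
        mtr <- f(t, ci_method = method)
        expect_lte(mtr$ci_low, mtr$estimate)
        expect_gte(mtr$ci_high, mtr$estimate)
        expect_gte(mtr$ci_low, 0)
        expect_lte(mtr$ci_high, 1)
      }
      k <- cohen_kappa(t)
      expect_true(k$ci_low <= k$estimate && k$estimate <= k$ci_high)
    }
  }
})

test_that("error counts match published totals and the double-count identity", {
  e <- error_counts(contingency_2x2(4844, 895, 642, 10929))
  expect_equal(c(e$fp, e$fn, e$total), c(895, 642, 1537))
  e2 <- error_counts(contingency_2x2(2442, 90, 246, 14532))
  expect_equal(e2$total, 336)
  expect_equal(error_counts(contingency_2x2(1, 0, 0, 1))$total, 0)
  # each misclassified patient is an fn in its gold group and an fp in its
  # predicted group, so totals across groups double-count errors exactly
  set.seed(55)
  ids <- sprintf("P%03d", 1:80)
  pred <- data.frame(patient_id = ids,
                     group = sample(treatment_groups(), 80, replace = TRUE))
  gold <- data.frame(patient_id = ids,
                     group = sample(treatment_groups(), 80, replace = TRUE))
  tot <- sum(vapply(treatment_groups(), function(g) {
    error_counts(build_contingency(pred, gold, g))$total
  }, numeric(1)))
  expect_equal(tot, 2 * sum(pred$group != gold$group))
})

test_that("evaluate on identical labelings is perfect across all groups", {
  set.seed(60)
  ids <- sprintf("P%03d", 1:50)
  gold <- data.frame(patient_id = ids,
                     group = sample(treatment_groups(), 50, replace = TRUE,
                                    prob = rep(1/8, 8)))
  rep_ <- evaluate(gold, gold)
  for (g in names(rep_$groups)) {
    expect_equal(rep_$groups[[g]]$agreement$estimate, 1.0)
    expect_equal(rep_$groups[[g]]$errors$total, 0)
  }
})

test_that("the report renderer prints the published table shape", {
  rep_ <- evaluate_counts(published_counts())
  lines <- format_eval_report(rep_)
  expect_true(any(grepl("^n_patients: 17310$", lines)))
  expect_true(any(grepl("^\\[platinum_doublet\\]$", lines)))
  expect_true(any(grepl("^kappa: 0.92", lines[grep("^\\[platinum_doublet\\]$", lines) + 3])))
  expect_true(any(grepl("^total_errors: 1537", lines)))
})
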