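#' A one-vs-rest 2x2 contingency table
#'
#' Counts are oriented with the algorithm (text mining) on rows and the
#' gold standard (manual review) on columns: `tp` = algorithm yes / gold
#' yes, `fp` = algorithm yes / gold no, `fn` = algorithm no / gold yes,
#' `tn` = algorithm no / gold no.
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return A list of class `ct_table2x2` with an `n` element.
#' @export
#' @examples
#' contingency_2x2(2442, 90, 246, 14532)
contingency_2x2 <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("tp, fp, fn, tn must be non-negative integers", call. = FALSE)
  }
  counts <- as.integer(counts)
  names(counts) <- c("tp", "fp", "fn", "tn")
  structure(as.list(counts), n = sum(counts), class = "ct_table2x2")
}

tab_n <- function(t) attr(t, "n")

#' Build a one-vs-rest contingency table from two labelings
#'
#' Dichotomizes both the algorithm and gold labelings at `group` and
#' cross-tabulates over the shared patient set.
#'
#' @param pred Data frame with columns `patient_id`, `group` (algorithm).
#' @param gold Data frame with columns `patient_id`, `group` (manual
#'   review / gold standard).
#' @param group The treatment group to dichotomize at.
#' @return A `ct_table2x2`; `tp + fp + fn + tn` equals the number of
#'   patients.
#' @export
build_contingency <- function(pred, gold, group) {
  group <- match.arg(group, TREATMENT_GROUPS)
  p <- label_vector(pred, "pred")
  g <- label_vector(gold, "gold")
  only_p <- setdiff(names(p), names(g))
  only_g <- setdiff(names(g), names(p))
  if (length(only_p) || length(only_g)) {
    stop(sprintf(
      "patient sets differ: %d only in pred (%s), %d only in gold (%s)",
      length(only_p), paste(utils::head(only_p, 5), collapse = ", "),
      length(only_g), paste(utils::head(only_g, 5), collapse = ", ")),
      call. = FALSE)
  }
  g <- g[names(p)]
  py <- p == group; gy <- g == group
  contingency_2x2(sum(py & gy), sum(py & !gy), sum(!py & gy), sum(!py & !gy))
}

label_vector <- function(x, what) {
  if (!all(c("patient_id", "group") %in% names(x))) {
    stop(sprintf("`%s` needs columns patient_id and group", what), call. = FALSE)
  }
  ids <- as.character(x$patient_id)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate patient_id in `%s`", what), call. = FALSE)
  }
  stats::setNames(as.character(x$group), ids)
}

#' Confidence interval for a binomial proportion
#'
#' Wilson score (default, via [stats::prop.test()] without continuity
#' correction), Wald, or exact Clopper-Pearson (via
#' [stats::binom.test()]) intervals.
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param method `"wilson"`, `"wald"`, or `"exact"`.
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @export
proportion_ci <- function(x, n, method = c("wilson", "wald", "exact"), conf = 0.95) {
  method <- match.arg(method)
  p <- x / n
  ci <- switch(method,
    # prop.test warns about its chi-squared test at extreme counts; only
    # the Wilson interval is used here
    wilson = as.numeric(suppressWarnings(
      stats::prop.test(x, n, correct = FALSE, conf.level = conf))$conf.int),
    exact = as.numeric(stats::binom.test(x, n, conf.level = conf)$conf.int),
    wald = {
      z <- stats::qnorm(1 - (1 - conf) / 2)
      se <- sqrt(p * (1 - p) / n)
      c(max(0, p - z * se), min(1, p + z * se))
    })
  # guard tiny numerical overshoot around the point estimate
  c(min(ci[1], p), max(ci[2], p))
}

new_metric <- function(estimate, ci, n) {
  structure(list(estimate = estimate, ci_low = ci[1], ci_high = ci[2], n = n),
            class = "ct_metric")
}

#' @export
print.ct_metric <- function(x, ...) {
  cat(sprintf("%.4f (95%% CI %.4f, %.4f; n = %d)\n",
              x$estimate, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Percent agreement between algorithm and gold standard
#'
#' `(tp + tn) / n`: the proportion of patients on which the two methods
#' agree for a one-vs-rest dichotomization.
#'
#' @param t A `ct_table2x2`.
#' @param ci_method Proportion CI method, see [proportion_ci()].
#' @return A `ct_metric` (proportion scale).
#' @export
percent_agreement <- function(t, ci_method = "wilson") {
  stopifnot(inherits(t, "ct_table2x2"))
  n <- tab_n(t)
  if (n == 0) stop("percent agreement undefined for an empty table", call. = FALSE)
  x <- t$tp + t$tn
  new_metric(x / n, proportion_ci(x, n, ci_method), n)
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' Chance-corrected agreement: `kappa = (po - pe) / (1 - pe)` with
#' observed agreement `po = (tp + tn)/n` and expected agreement `pe`
#' computed from the table marginals. The confidence interval uses the
#' large-sample standard error
#' `sqrt(po (1 - po) / n) / (1 - pe)`.
#'
#' @inheritParams percent_agreement
#' @return A `ct_metric` with estimate in `[-1, 1]`.
#' @export
#' @examples
#' cohen_kappa(contingency_2x2(2442, 90, 246, 14532))  # 0.92
cohen_kappa <- function(t, ci_method = "wilson") {
  stopifnot(inherits(t, "ct_table2x2"))
  n <- tab_n(t)
  if (n == 0) stop("kappa undefined for an empty table", call. = FALSE)
  po <- (t$tp + t$tn) / n
  pe <- ((t$tp + t$fp) * (t$tp + t$fn) + (t$fn + t$tn) * (t$fp + t$tn)) / n^2
  if (pe >= 1) stop("kappa undefined: degenerate marginals (expected agreement = 1)",
                    call. = FALSE)
  k <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / n) / (1 - pe)
  z <- stats::qnorm(0.975)
  new_metric(k, c(max(-1, k - z * se), min(1, k + z * se)), n)
}

rate_metric <- function(num, den, name, ci_method) {
  if (den == 0) {
    stop(sprintf("%s undefined: empty denominator", name), call. = FALSE)
  }
  new_metric(num / den, proportion_ci(num, den, ci_method), den)
}

#' Diagnostic accuracy metrics from a 2x2 table
#'
#' Sensitivity `tp/(tp+fn)` (proportion of truly treated patients the
#' algorithm identifies), specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)`, negative predictive value `tn/(tn+fn)`; each with
#' a binomial confidence interval over its own denominator.
#'
#' @inheritParams percent_agreement
#' @return A `ct_metric`.
#' @name accuracy_metrics
NULL

#' @rdname accuracy_metrics
#' @export
sensitivity <- function(t, ci_method = "wilson") {
  stopifnot(inherits(t, "ct_table2x2"))
  rate_metric(t$tp, t$tp + t$fn, "sensitivity", ci_method)
}

#' @rdname accuracy_metrics
#' @export
specificity <- function(t, ci_method = "wilson") {
  stopifnot(inherits(t, "ct_table2x2"))
  rate_metric(t$tn, t$tn + t$fp, "specificity", ci_method)
}

#' @rdname accuracy_metrics
#' @export
ppv <- function(t, ci_method = "wilson") {
  stopifnot(inherits(t, "ct_table2x2"))
  rate_metric(t$tp, t$tp + t$fp, "ppv", ci_method)
}

#' @rdname accuracy_metrics
#' @export
npv <- function(t, ci_method = "wilson") {
  stopifnot(inherits(t, "ct_table2x2"))
  rate_metric(t$tn, t$tn + t$fn, "npv", ci_method)
}

#' False positive, false negative, and total error counts
#'
#' @inheritParams percent_agreement
#' @return Named list: `fp`, `fn`, `total` counts and `fp_pct`, `fn_pct`,
#'   `total_pct` as percentages of n.
#' @export
error_counts <- function(t) {
  stopifnot(inherits(t, "ct_table2x2"))
  n <- tab_n(t)
  list(fp = t$fp, fn = t$fn, total = t$fp + t$fn,
       fp_pct = 100 * t$fp / n, fn_pct = 100 * t$fn / n,
       total_pct = 100 * (t$fp + t$fn) / n)
}

#' Full eight-group evaluation of algorithm vs gold labels
#'
#' Builds the one-vs-rest contingency table for each of the eight
#' treatment groups and computes percent agreement, Cohen's kappa,
#' sensitivity, specificity, PPV, NPV, and error counts for each.
#'
#' @inheritParams build_contingency
#' @param ci_method Proportion CI method.
#' @return A list of class `ct_eval_report`: `n`, `ci_method`, and
#'   `groups`, a per-group list of `table` plus the metric objects.
#' @export
evaluate <- function(pred, gold, ci_method = "wilson") {
  tabs <- lapply(TREATMENT_GROUPS, function(g) build_contingency(pred, gold, g))
  names(tabs) <- TREATMENT_GROUPS
  evaluate_tables(tabs, ci_method)
}

#' Evaluate directly from contingency counts
#'
#' Counts-only entry point: reproduces the full report from per-group
#' 2x2 count quadruples (e.g. counts transcribed from a published
#' agreement table) without patient-level labels.
#'
#' @param counts Data frame with columns `group`, `tp`, `fp`, `fn`, `tn`,
#'   one row per treatment group.
#' @inheritParams evaluate
#' @return A `ct_eval_report`.
#' @export
evaluate_counts <- function(counts, ci_method = "wilson") {
  need <- c("group", "tp", "fp", "fn", "tn")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop(sprintf("counts are missing column(s): %s",
                                 paste(miss, collapse = ", ")), call. = FALSE)
  tabs <- lapply(seq_len(nrow(counts)), function(i) {
    contingency_2x2(as.numeric(counts$tp[i]), as.numeric(counts$fp[i]),
                    as.numeric(counts$fn[i]), as.numeric(counts$tn[i]))
  })
  names(tabs) <- as.character(counts$group)
  evaluate_tables(tabs, ci_method)
}

evaluate_tables <- function(tabs, ci_method = "wilson") {
  ns <- vapply(tabs, tab_n, numeric(1))
  if (length(unique(ns)) != 1L) {
    stop("all per-group tables must share the same total n", call. = FALSE)
  }
  groups <- lapply(tabs, function(t) {
    list(table = t,
         agreement = percent_agreement(t, ci_method),
         kappa = cohen_kappa(t, ci_method),
         sensitivity = sensitivity(t, ci_method),
         specificity = specificity(t, ci_method),
         ppv = ppv(t, ci_method),
         npv = npv(t, ci_method),
         errors = error_counts(t))
  })
  structure(list(n = unname(ns[1]), ci_method = ci_method, groups = groups),
            class = "ct_eval_report")
}

#' Round half away from zero
#'
#' Display rounding used throughout the report renderer (half-up at the
#' given number of decimals), matching how registry agreement tables are
#' conventionally printed; R's [round()] rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Render an evaluation report as structured key-value text
#'
#' One block per treatment group with the contingency counts, agreement
#' and kappa (with CIs), the four accuracy metrics, and error counts.
#' Percentages print to one decimal, kappa to two (half-up).
#'
#' @param report A `ct_eval_report`.
#' @return Character vector of lines, invisibly also printable via
#'   `print()`.
#' @export
format_eval_report <- function(report) {
  stopifnot(inherits(report, "ct_eval_report"))
  pct <- function(m) sprintf("%.1f (%.1f, %.1f)",
                             round_half_up(100 * m$estimate, 1),
                             round_half_up(100 * m$ci_low, 1),
                             round_half_up(100 * m$ci_high, 1))
  lines <- c(sprintf("n_patients: %d", report$n),
             sprintf("ci_method: %s", report$ci_method))
  for (g in names(report$groups)) {
    x <- report$groups[[g]]
    t <- x$table
    lines <- c(lines, "",
      sprintf("[%s]", g),
      sprintf("counts: tp=%d fp=%d fn=%d tn=%d", t$tp, t$fp, t$fn, t$tn),
      sprintf("agreement_pct: %s", pct(x$agreement)),
      sprintf("kappa: %.2f (%.2f, %.2f)",
              round_half_up(x$kappa$estimate, 2),
              round_half_up(x$kappa$ci_low, 2),
              round_half_up(x$kappa$ci_high, 2)),
      sprintf("sensitivity_pct: %s", pct(x$sensitivity)),
      sprintf("specificity_pct: %s", pct(x$specificity)),
      sprintf("ppv_pct: %s", pct(x$ppv)),
      sprintf("npv_pct: %s", pct(x$npv)),
      sprintf("false_positives: %d (%.1f)", x$errors$fp,
              round_half_up(x$errors$fp_pct, 1)),
      sprintf("false_negatives: %d (%.1f)", x$errors$fn,
              round_half_up(x$errors$fn_pct, 1)),
      sprintf("total_errors: %d (%.1f)", x$errors$total,
              round_half_up(x$errors$total_pct, 1)))
  }
  lines
}

#' @export
print.ct_eval_report <- function(x, ...) {
  cat(format_eval_report(x), sep = "\n")
  invisible(x)
}
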