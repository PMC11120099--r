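# Diagnostic-accuracy machinery: confusion-matrix metrics with Wilson
# intervals, Mann-Whitney AUC, DeLong variance/covariance and paired AUC
# comparison, Youden-optimal cut-offs, and the per-rule accuracy report.

#' Wilson score interval for a binomial proportion
#'
#' @param x number of successes (vectorised).
#' @param n number of trials.
#' @param level confidence level, default 0.95.
#' @return matrix with columns `low`, `high`.
#' @export
wilson_ci <- function(x, n, level = 0.95) {
  stopifnot(all(x >= 0), all(n > 0), all(x <= n))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  cbind(low = (centre - half) / denom, high = (centre + half) / denom)
}

#' Sensitivity, specificity and predictive values with Wilson intervals
#'
#' @param tp,fp,tn,fn confusion-matrix counts.
#' @param level confidence level for the Wilson intervals.
#' @return list of class `"accuracy_metrics"`; each of `sn`, `sp`, `ppv`,
#'   `npv` is `c(estimate, low, high)`, or `NA`s when its denominator is
#'   zero (the other metrics are still returned).
#' @examples
#' predictive_metrics(tp = 8, fn = 2, tn = 9, fp = 3)
#' @export
predictive_metrics <- function(tp, fp, tn, fn, level = 0.95) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion-matrix counts must be non-negative integers", call. = FALSE)
  one <- function(x, n) {
    if (n == 0) return(c(estimate = NA_real_, low = NA_real_, high = NA_real_))
    ci <- wilson_ci(x, n, level)
    c(estimate = x / n, low = unname(ci[1, "low"]), high = unname(ci[1, "high"]))
  }
  structure(list(sn = one(tp, tp + fn), sp = one(tn, tn + fp),
                 ppv = one(tp, tp + fp), npv = one(tn, tn + fn),
                 level = level,
                 counts = counts),
            class = "accuracy_metrics")
}

.check_roc_input <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.logical(labels[keep])
  if (!any(labels) || all(labels))
    stop("ROC input needs at least one positive and one negative", call. = FALSE)
  list(scores = scores, labels = labels, n_excluded = sum(!keep))
}

#' Mann-Whitney AUC
#'
#' Area under the ROC curve as the concordance probability: the fraction
#' of (positive, negative) pairs in which the positive scores higher, with
#' half credit for ties. Patients with missing scores or labels are
#' excluded (count available via `attr(, "n_excluded")`).
#'
#' @param scores numeric score per patient (higher = more disease-like).
#' @param labels logical (or 0/1) outcome per patient.
#' @return the AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(scores, labels) {
  d <- .check_roc_input(scores, labels)
  n1 <- sum(d$labels); n0 <- sum(!d$labels)
  r <- rank(d$scores)  # midranks give the half-credit tie convention
  auc <- (sum(r[d$labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(auc, n_excluded = d$n_excluded)
}

# Placement values: V10[i] = P-hat(score_i beats a random negative),
# V01[j] = P-hat(a random positive beats score_j); ties count 1/2.
.delong_placements <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  v10 <- vapply(pos, function(s) mean((s > neg) + 0.5 * (s == neg)), numeric(1))
  v01 <- vapply(neg, function(s) mean((pos > s) + 0.5 * (pos == s)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong confidence interval for an AUC
#'
#' Nonparametric AUC variance from the empirical variances of the
#' placement values, `Var = S10/n1 + S01/n0`, with a normal-theory
#' interval clipped to \[0, 1\]. Perfectly separated data have zero
#' estimated variance; the interval then degenerates to the point and is
#' flagged.
#'
#' @inheritParams auc_mann_whitney
#' @param level confidence level.
#' @return list: `auc`, `var_auc`, `ci_low`, `ci_high`, `level`,
#'   `degenerate` (logical), `n_pos`, `n_neg`, `n_excluded`.
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  d <- .check_roc_input(scores, labels)
  n1 <- sum(d$labels); n0 <- sum(!d$labels)
  if (n1 < 2 || n0 < 2)
    stop("delong_ci: need at least two positives and two negatives", call. = FALSE)
  pl <- .delong_placements(d$scores, d$labels)
  v <- stats::var(pl$v10) / n1 + stats::var(pl$v01) / n0
  z <- stats::qnorm(1 - (1 - level) / 2)
  degenerate <- v <= .Machine$double.eps
  half <- if (degenerate) 0 else z * sqrt(v)
  list(auc = pl$auc, var_auc = v,
       ci_low = max(0, pl$auc - half), ci_high = min(1, pl$auc + half),
       level = level, degenerate = degenerate,
       n_pos = n1, n_neg = n0, n_excluded = d$n_excluded)
}

#' DeLong paired comparison of two AUCs
#'
#' Two-sided test of equal AUC for two scores measured on the same
#' patients, using the placement-value covariance on the
#' pairwise-complete subset:
#' `z = (AUC_A - AUC_B) / sqrt(Var_A + Var_B - 2 Cov)`.
#'
#' @param scores_a,scores_b numeric scores on the same patients.
#' @param labels outcome labels.
#' @return list: `p_value`, `z`, `auc_a`, `auc_b`, `var_diff`,
#'   `degenerate` (zero variance of the difference; `p_value = 1` by
#'   convention), `n_used`.
#' @export
delong_paired_pvalue <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  keep <- !is.na(scores_a) & !is.na(scores_b) & !is.na(labels)
  a <- scores_a[keep]; b <- scores_b[keep]; lab <- as.logical(labels[keep])
  if (!any(lab) || all(lab))
    stop("paired AUC comparison needs both classes", call. = FALSE)
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 < 2 || n0 < 2)
    stop("paired AUC comparison needs >= 2 per class", call. = FALSE)
  pa <- .delong_placements(a, lab)
  pb <- .delong_placements(b, lab)
  var_diff <- (stats::var(pa$v10) + stats::var(pb$v10) -
                 2 * stats::cov(pa$v10, pb$v10)) / n1 +
              (stats::var(pa$v01) + stats::var(pb$v01) -
                 2 * stats::cov(pa$v01, pb$v01)) / n0
  if (var_diff <= .Machine$double.eps) {
    return(list(p_value = 1, z = 0, auc_a = pa$auc, auc_b = pb$auc,
                var_diff = var_diff, degenerate = TRUE, n_used = n1 + n0))
  }
  z <- (pa$auc - pb$auc) / sqrt(var_diff)
  list(p_value = 2 * stats::pnorm(-abs(z)), z = z,
       auc_a = pa$auc, auc_b = pb$auc, var_diff = var_diff,
       degenerate = FALSE, n_used = n1 + n0)
}

#' Empirical ROC curve points
#'
#' Sensitivity and specificity at every observed score value under the
#' positivity rule "score >= threshold".
#'
#' @inheritParams auc_mann_whitney
#' @return data frame with columns `threshold`, `sn`, `sp`,
#'   `one_minus_sp`, sorted by increasing threshold.
#' @export
roc_points <- function(scores, labels) {
  d <- .check_roc_input(scores, labels)
  thr <- sort(unique(d$scores))
  n1 <- sum(d$labels); n0 <- sum(!d$labels)
  sn <- vapply(thr, function(t) sum(d$scores >= t & d$labels) / n1, numeric(1))
  sp <- vapply(thr, function(t) sum(d$scores < t & !d$labels) / n0, numeric(1))
  data.frame(threshold = thr, sn = sn, sp = sp, one_minus_sp = 1 - sp)
}

#' Youden-optimal cut-off
#'
#' Exhaustive search over observed score values for the threshold
#' maximising Youden's J = Sn + Sp - 1 under the rule
#' "positive iff score >= threshold"; ties are broken toward the lowest
#' threshold.
#'
#' @inheritParams auc_mann_whitney
#' @return list: `threshold`, `j`, `sn`, `sp`.
#' @export
youden_threshold <- function(scores, labels) {
  rp <- roc_points(scores, labels)
  j <- rp$sn + rp$sp - 1
  i <- which.max(j)  # which.max takes the first (lowest threshold) on ties
  list(threshold = rp$threshold[i], j = j[i], sn = rp$sn[i], sp = rp$sp[i])
}

#' Per-rule diagnostic-accuracy report
#'
#' For each threshold rule: the AUC of the underlying continuous score
#' with its DeLong interval, and Sn/Sp/PPV/NPV with Wilson intervals at
#' the rule's cut-off. Patients with an undefined score are excluded per
#' rule (complete-case per score) and counted in `n_excluded` — the
#' mechanism by which an ultrasound-dependent score is evaluated on the
#' ultrasound subset only.
#'
#' @param scored_cohort a cohort from [score_cohort()] (needs
#'   `vap_confirmed` plus the score columns).
#' @param rules named list of [threshold_rule()]s; default
#'   [default_threshold_rules()].
#' @param level confidence level.
#' @return data frame of class `"accuracy_report"`, one row per rule:
#'   `score`, `cutoff`, `comparison`, `auc`, `auc_lo`, `auc_hi`, `sn`,
#'   `sn_lo`, `sn_hi`, `sp`, `sp_lo`, `sp_hi`, `ppv`, `ppv_lo`, `ppv_hi`,
#'   `npv`, `npv_lo`, `npv_hi`, `n_included`, `n_excluded`.
#' @export
evaluate_panel <- function(scored_cohort, rules = default_threshold_rules(),
                           level = 0.95) {
  stopifnot("vap_confirmed" %in% names(scored_cohort))
  rows <- lapply(rules, function(rule) {
    s <- scored_cohort[[rule$score_name]]
    if (is.null(s)) stop(sprintf("score column '%s' missing", rule$score_name),
                         call. = FALSE)
    keep <- !is.na(s)
    if (!any(keep)) stop(sprintf("no patient has a defined '%s'", rule$score_name),
                         call. = FALSE)
    s <- s[keep]
    y <- scored_cohort$vap_confirmed[keep] == 1
    dl <- delong_ci(s, y, level)
    pred <- classify(s, rule) == "positive"
    pm <- predictive_metrics(tp = sum(pred & y), fp = sum(pred & !y),
                             tn = sum(!pred & !y), fn = sum(!pred & y),
                             level = level)
    data.frame(score = rule$score_name, cutoff = rule$cutoff,
               comparison = rule$comparison,
               auc = dl$auc, auc_lo = dl$ci_low, auc_hi = dl$ci_high,
               sn = pm$sn["estimate"], sn_lo = pm$sn["low"], sn_hi = pm$sn["high"],
               sp = pm$sp["estimate"], sp_lo = pm$sp["low"], sp_hi = pm$sp["high"],
               ppv = pm$ppv["estimate"], ppv_lo = pm$ppv["low"], ppv_hi = pm$ppv["high"],
               npv = pm$npv["estimate"], npv_lo = pm$npv["low"], npv_hi = pm$npv["high"],
               n_included = sum(keep), n_excluded = sum(!keep),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("accuracy_report", "data.frame")
  out
}

#' Descriptive group comparison between VAP and no-VAP
#'
#' The descriptive-table dispatcher: categorical variables are tested with
#' [association_pvalue()] (chi-squared or Fisher), normally distributed
#' continuous variables with Welch's t-test, and skewed continuous
#' variables with the Mann-Whitney U test (normal approximation with tie
#' correction).
#'
#' @param cohort cohort data frame with `vap_confirmed`.
#' @param variable column name to compare.
#' @param kind `"categorical"`, `"continuous_normal"`, or
#'   `"continuous_skewed"`.
#' @return two-sided p-value.
#' @export
group_compare <- function(cohort, variable,
                          kind = c("categorical", "continuous_normal",
                                   "continuous_skewed")) {
  kind <- match.arg(kind)
  stopifnot(variable %in% names(cohort), "vap_confirmed" %in% names(cohort))
  x <- cohort[[variable]]
  g <- cohort$vap_confirmed == 1
  keep <- !is.na(x)
  x <- x[keep]; g <- g[keep]
  if (!any(g) || all(g)) stop("group_compare: one group is empty", call. = FALSE)
  switch(kind,
    categorical = association_pvalue(table(x, factor(g, c(TRUE, FALSE)))),
    continuous_normal = stats::t.test(x[g], x[!g])$p.value,
    continuous_skewed = {
      if (stats::var(x) == 0) 1 else   # all observations tied
        stats::wilcox.test(x[g], x[!g], exact = FALSE, correct = FALSE)$p.value
    })
}

#' Write an accuracy report to CSV and/or JSON
#'
#' @param report an `"accuracy_report"`.
#' @param csv,json optional output paths.
#' @return the report, invisibly.
#' @export
write_accuracy_report <- function(report, csv = NULL, json = NULL) {
  if (!is.null(csv)) utils::write.csv(report, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(report, json, dataframe = "rows", digits = NA,
                         pretty = TRUE)
  invisible(report)
}
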