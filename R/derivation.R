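# Contingency-table statistics and the log-odds-ratio point-assignment
# procedure used to construct the ultrasound/biomarker score from a cohort.

.as_ct <- function(ct) {
  if (is.matrix(ct)) ct <- c(a = ct[1, 1], b = ct[1, 2], c = ct[2, 1], d = ct[2, 2])
  ct <- unlist(ct[c("a", "b", "c", "d")])
  if (any(is.na(ct)) || any(ct < 0) || any(ct != round(ct)))
    stop("contingency table cells must be non-negative integers", call. = FALSE)
  if (sum(ct) == 0) stop("empty contingency table", call. = FALSE)
  ct
}

#' 2x2 contingency table
#'
#' Cross-counts of a feature level vs its reference level against the
#' confirmed-VAP label: `a` = level & VAP, `b` = level & no-VAP,
#' `c` = reference & VAP, `d` = reference & no-VAP.
#'
#' @param a,b,c,d non-negative integer counts.
#' @return named integer vector of class `"contingency_table"`.
#' @export
contingency_table <- function(a, b, c, d) {
  ct <- .as_ct(list(a = a, b = b, c = c, d = d))
  if (ct["a"] + ct["c"] == 0 || ct["b"] + ct["d"] == 0)
    stop("contingency_table: one outcome group is empty", call. = FALSE)
  structure(ct, class = "contingency_table")
}

#' Odds ratio with Wald confidence interval
#'
#' Point estimate `(a d)/(b c)` of the odds ratio, with a Wald interval on
#' the log scale, `exp(log OR +/- z * SE)`, `SE = sqrt(1/a+1/b+1/c+1/d)`.
#' When any cell is zero the Haldane--Anscombe correction adds 0.5 to every
#' cell (estimate and interval alike) and the result is flagged
#' `corrected = TRUE`.
#'
#' @param ct a [contingency_table()] (or anything [contingency_table()]
#'   accepts via `a`,`b`,`c`,`d` names).
#' @param level confidence level, default 0.95.
#' @return list of class `"or_result"`: `or_estimate`, `log_or`, `se`,
#'   `ci_low`, `ci_high`, `level`, `corrected`.
#' @examples
#' odds_ratio(contingency_table(47, 21, 1, 7))  # OR 15.7 [1.81-136]
#' @export
odds_ratio <- function(ct, level = 0.95) {
  ct <- .as_ct(ct)
  if (ct["a"] + ct["c"] == 0 || ct["b"] + ct["d"] == 0)
    stop("odds_ratio: one outcome group is empty", call. = FALSE)
  stopifnot(level > 0, level < 1)
  corrected <- any(ct == 0)
  w <- if (corrected) ct + 0.5 else ct
  est <- (w["a"] * w["d"]) / (w["b"] * w["c"])
  se <- sqrt(sum(1 / w))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(or_estimate = unname(est), log_or = unname(log(est)),
                 se = unname(se),
                 ci_low = unname(exp(log(est) - z * se)),
                 ci_high = unname(exp(log(est) + z * se)),
                 level = level, corrected = corrected),
            class = "or_result")
}

#' Wald confidence interval for an odds ratio
#'
#' @inheritParams odds_ratio
#' @return numeric vector `c(ci_low, ci_high)`.
#' @export
or_wald_ci <- function(ct, level = 0.95) {
  res <- odds_ratio(ct, level = level)
  c(ci_low = res$ci_low, ci_high = res$ci_high)
}

#' Association p-value for an r x 2 table
#'
#' Two-sided test of association between a categorical feature and the
#' VAP label: Fisher's exact test when any expected cell count is below 5,
#' otherwise Pearson's chi-squared test (no continuity correction). For
#' tables with more than two rows the chi-squared branch has r-1 degrees
#' of freedom and the Fisher branch uses its network generalisation.
#'
#' @param x a [contingency_table()], a 2x2/r x 2 count matrix.
#' @return two-sided p-value.
#' @export
association_pvalue <- function(x) {
  m <- if (inherits(x, "contingency_table") ||
           (!is.matrix(x) && !is.null(names(x)))) {
    ct <- .as_ct(x)
    matrix(ct[c("a", "b", "c", "d")], nrow = 2, byrow = TRUE)
  } else {
    as.matrix(x)
  }
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("association_pvalue: degenerate table (zero margin)", call. = FALSE)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    stats::fisher.test(m)$p.value
  } else {
    stats::chisq.test(m, correct = FALSE)$p.value
  }
}

#' Cross-tabulate a cohort feature level against its reference
#'
#' Builds the 2x2 table of (level vs reference) by (VAP vs no-VAP) from a
#' cohort data frame. Lung-ultrasound features (`consolidation_type`,
#' `size_band`, `laterality`, `bronchogram`) are restricted to patients in
#' whom LUS was performed.
#'
#' @param cohort cohort data frame (schema of [read_cohort()]); needs a
#'   `vap_confirmed` column.
#' @param feature name of a categorical column.
#' @param level the exposure level counted in cells `a`, `b`.
#' @param reference the reference level counted in cells `c`, `d`.
#' @return a [contingency_table()].
#' @export
feature_contingency <- function(cohort, feature, level, reference) {
  stopifnot(feature %in% names(cohort), "vap_confirmed" %in% names(cohort))
  if (identical(level, reference))
    stop("feature_contingency: level and reference must differ", call. = FALSE)
  lus_features <- c("consolidation_type", "size_band", "laterality", "bronchogram")
  if (feature %in% lus_features && "lus_performed" %in% names(cohort))
    cohort <- cohort[cohort$lus_performed == 1, , drop = FALSE]
  x <- cohort[[feature]]
  for (lv in c(level, reference))
    if (!any(!is.na(x) & x == lv))
      stop(sprintf("feature_contingency: category '%s' absent from column '%s'",
                   lv, feature), call. = FALSE)
  vap <- cohort$vap_confirmed == 1
  contingency_table(
    a = sum(x == level & vap, na.rm = TRUE),
    b = sum(x == level & !vap, na.rm = TRUE),
    c = sum(x == reference & vap, na.rm = TRUE),
    d = sum(x == reference & !vap, na.rm = TRUE))
}

# round half away from zero (base round() rounds half to even)
.round_half_up <- function(x) floor(x + 0.5)

#' Assign integer points from log-odds ratios
#'
#' The score-construction step: given the odds ratio of each feature level
#' against its reference, points are assigned proportionally to the log
#' odds ratio. The scaling unit is `max(log OR) / max_points`, so the
#' strongest level receives `max_points`; every other level receives its
#' log OR divided by the unit, rounded half away from zero and clipped to
#' `[0, max_points]`. Levels with OR at or below 1 (no positive
#' association) receive 0.
#'
#' @param feature_ors named list of [odds_ratio()] results, or a named
#'   numeric vector of odds ratios, one per non-reference level.
#' @param max_points largest point value to award (>= 1).
#' @return list of class `"derived_points"`: `points` (named integer
#'   vector), `scaling_unit` (log-OR per point), `log_or` (provenance).
#' @examples
#' points_from_log_or(c(static = 7.37, dynamic = 266), max_points = 3)
#' @export
points_from_log_or <- function(feature_ors, max_points) {
  stopifnot(max_points >= 1)
  ors <- vapply(feature_ors,
                function(x) if (inherits(x, "or_result")) x$or_estimate else as.numeric(x),
                numeric(1))
  if (any(ors < 0)) stop("odds ratios must be non-negative", call. = FALSE)
  log_or <- log(ors)
  if (max(log_or) <= 0)
    stop("degenerate score: no level has an odds ratio above 1", call. = FALSE)
  unit <- max(log_or) / max_points
  pts <- .round_half_up(log_or / unit)
  pts <- pmin(pmax(pts, 0), max_points)
  pts[ors <= 1] <- 0
  structure(list(points = stats::setNames(as.integer(pts), names(ors)),
                 scaling_unit = unit, log_or = log_or),
            class = "derived_points")
}

#' Derive a full score table from a cohort
#'
#' Runs [feature_contingency()], [odds_ratio()] and [points_from_log_or()]
#' for each requested categorical feature, producing a points table in the
#' shape of the published ultrasound/biomarker score: reference levels get
#' 0 points, and each feature's strongest level gets that feature's
#' maximum.
#'
#' @param cohort cohort data frame with `vap_confirmed`.
#' @param features named list: for each feature column, a list with
#'   `levels` (non-reference levels), `reference`, and `max_points`.
#'   Defaults cover the four LUS findings with the published maxima
#'   (type 2, size 2, laterality 2, bronchogram 3).
#' @return list of class `"derived_score_table"`: per feature the points,
#'   scaling unit and OR provenance.
#' @export
derive_score_table <- function(cohort, features = default_derivation_features()) {
  out <- lapply(names(features), function(f) {
    sp <- features[[f]]
    ors <- lapply(sp$levels, function(lv)
      odds_ratio(feature_contingency(cohort, f, lv, sp$reference)))
    names(ors) <- sp$levels
    dp <- points_from_log_or(ors, sp$max_points)
    pts <- c(stats::setNames(0L, sp$reference), dp$points)
    list(points = pts, scaling_unit = dp$scaling_unit,
         reference = sp$reference,
         or = vapply(ors, `[[`, numeric(1), "or_estimate"))
  })
  names(out) <- names(features)
  structure(out, class = "derived_score_table")
}

#' Default feature plan for score derivation
#'
#' The four LUS findings with their reference categories (no consolidation
#' / no bronchogram) and published point maxima.
#'
#' @return named list usable as the `features` argument of
#'   [derive_score_table()].
#' @export
default_derivation_features <- function() {
  list(
    consolidation_type = list(levels = c("subpleural", "lobar"),
                              reference = "none", max_points = 2),
    size_band          = list(levels = c("lt15", "s15to20", "gt20"),
                              reference = "none", max_points = 2),
    laterality         = list(levels = c("bilateral", "unilateral"),
                              reference = "none", max_points = 2),
    bronchogram        = list(levels = c("static", "dynamic"),
                              reference = "none", max_points = 3))
}

#' Serialise a derived score table to JSON
#'
#' @param table a `"derived_score_table"`.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  payload <- lapply(unclass(table), function(f)
    list(points = as.list(f$points), scaling_unit = f$scaling_unit,
         reference = f$reference, or = as.list(f$or)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
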