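# canonical factor levels for the cohort schema
.secretions_levels   <- c("absent_minimal", "non_purulent", "purulent")
.radiography_levels  <- c("no_infiltrate", "patchy_diffuse", "localized")
.microbiology_levels <- c("negative", "positive", "positive_with_gram_match")
.consolidation_levels <- c("none", "subpleural", "lobar")
.size_levels          <- c("none", "lt15", "s15to20", "gt20")
.laterality_levels    <- c("none", "bilateral", "unilateral")
.bronchogram_levels   <- c("none", "static", "dynamic")

.score_names <- c("cpis", "lus_score", "cpis_lus", "cpis_pct", "cpis_plus")

#' Lung ultrasound exam findings
#'
#' Bundles the four categorical lung-ultrasound (LUS) findings scored for a
#' suspected ventilator-associated pneumonia (VAP) episode: consolidation
#' type, consolidation size band, laterality, and air bronchogram.
#' Structural invariants are enforced: an exam without a consolidation
#' cannot carry a size or a laterality (and, since an air bronchogram lives
#' inside a consolidation, cannot carry a bronchogram either).
#'
#' @param consolidation_type one of `"none"`, `"subpleural"`, `"lobar"`.
#' @param size_band one of `"none"`, `"lt15"` (< 15 mm), `"s15to20"`
#'   (15--20 mm), `"gt20"` (> 20 mm).
#' @param laterality one of `"none"`, `"bilateral"`, `"unilateral"`.
#' @param bronchogram one of `"none"`, `"static"`, `"dynamic"`.
#' @return a list of class `"lus_exam"`.
#' @examples
#' lus_exam("lobar", "gt20", "unilateral", "dynamic")
#' @export
lus_exam <- function(consolidation_type = "none", size_band = "none",
                     laterality = "none", bronchogram = "none") {
  consolidation_type <- match.arg(consolidation_type, .consolidation_levels)
  size_band   <- match.arg(size_band, .size_levels)
  laterality  <- match.arg(laterality, .laterality_levels)
  bronchogram <- match.arg(bronchogram, .bronchogram_levels)
  if (consolidation_type == "none" &&
      (size_band != "none" || laterality != "none")) {
    stop("lus_exam: size_band and laterality must be 'none' when there is no consolidation",
         call. = FALSE)
  }
  structure(list(consolidation_type = consolidation_type,
                 size_band = size_band, laterality = laterality,
                 bronchogram = bronchogram),
            class = "lus_exam")
}

#' A suspected-VAP patient episode
#'
#' One row of the analysis: the clinical, laboratory, microbiological and
#' (optionally) ultrasound measurements taken when VAP was suspected, plus
#' the adjudicated confirmed-VAP label. Missing optional inputs
#' (radiography, PCT, LUS) stay missing; downstream composites that need
#' them are reported as `NA`, never imputed.
#'
#' @param patient_id opaque identifier.
#' @param vap_confirmed logical; adjudicated final VAP diagnosis.
#' @param temperature core temperature, degrees Celsius (25--45).
#' @param wbc blood leukocytes per mm3.
#' @param band_forms band forms per mm3 (default 0).
#' @param pf_ratio PaO2/FiO2 ratio (> 0).
#' @param ards logical; acute respiratory distress syndrome present.
#' @param secretions `"absent_minimal"`, `"non_purulent"` or `"purulent"`.
#' @param radiography `"no_infiltrate"`, `"patchy_diffuse"`, `"localized"`,
#'   or `NA` if no chest radiograph was read.
#' @param microbiology `"negative"`, `"positive"` or
#'   `"positive_with_gram_match"` (tracheal-aspirate culture, with or
#'   without a concordant Gram stain).
#' @param pct serum procalcitonin in ng/mL, or `NA`.
#' @param lus a [lus_exam()] or `NULL` if no LUS was performed.
#' @return a list of class `"patient_record"`.
#' @export
patient_record <- function(patient_id, vap_confirmed, temperature, wbc,
                           band_forms = 0, pf_ratio, ards = FALSE,
                           secretions, radiography = NA, microbiology,
                           pct = NA, lus = NULL) {
  stopifnot(is.logical(vap_confirmed), length(vap_confirmed) == 1L)
  if (!is.finite(temperature) || temperature < 25 || temperature > 45)
    stop("patient_record: temperature must lie in [25, 45] degrees C", call. = FALSE)
  if (!is.finite(wbc) || wbc < 0)
    stop("patient_record: wbc must be non-negative", call. = FALSE)
  if (!is.finite(band_forms) || band_forms < 0)
    stop("patient_record: band_forms must be non-negative", call. = FALSE)
  if (!is.finite(pf_ratio) || pf_ratio <= 0)
    stop("patient_record: pf_ratio must be positive", call. = FALSE)
  secretions <- match.arg(secretions, .secretions_levels)
  if (!is.na(radiography))
    radiography <- match.arg(radiography, .radiography_levels)
  microbiology <- match.arg(microbiology, .microbiology_levels)
  if (!is.na(pct) && pct < 0)
    stop("patient_record: pct must be non-negative when present", call. = FALSE)
  if (!is.null(lus) && !inherits(lus, "lus_exam"))
    stop("patient_record: lus must be a lus_exam or NULL", call. = FALSE)
  structure(list(patient_id = as.character(patient_id),
                 vap_confirmed = vap_confirmed,
                 temperature = temperature, wbc = wbc,
                 band_forms = band_forms, pf_ratio = pf_ratio,
                 ards = isTRUE(ards), secretions = secretions,
                 radiography = radiography, microbiology = microbiology,
                 pct = pct, lus = lus),
            class = "patient_record")
}

# ---- vectorised component banding -------------------------------------
# Temperature bands leave printed gaps (36.0-36.5 and 38.4-38.5); bands are
# half-open and the residual gap maps to the clinically normal side:
#   <= 36.0 or >= 39.0 -> 2 ; [38.5, 39.0) -> 1 ; everything else -> 0.
.pts_temperature <- function(t) {
  ifelse(t <= 36 | t >= 39, 2L, ifelse(t >= 38.5, 1L, 0L))
}

# Leukocyte counts: 4000-11000/mm3 is the normal band; an abnormal count
# with >= 500 band forms/mm3 scores 2.
.pts_leukocytes <- function(wbc, bands) {
  abnormal <- wbc < 4000 | wbc > 11000
  ifelse(abnormal & bands >= 500, 2L, ifelse(abnormal, 1L, 0L))
}

# Oxygenation is two-valued: impaired P/F without ARDS scores 2, else 0.
.pts_oxygenation <- function(pf, ards) {
  ifelse(pf <= 240 & !ards, 2L, 0L)
}

.pts_enum <- function(x, levels) {
  out <- match(x, levels) - 1L
  out
}

#' Points for one CPIS component
#'
#' Maps a single measurement to its 0--2 point contribution in the Clinical
#' Pulmonary Infection Score. Continuous measurements are banded with
#' half-open intervals so that every value in the valid domain maps to
#' exactly one band.
#'
#' @param component one of `"temperature"`, `"leukocytes"`, `"oxygenation"`,
#'   `"secretions"`, `"radiography"`, `"microbiology"`.
#' @param value the component measurement: a temperature in degrees C, a
#'   WBC count per mm3, a P/F ratio, or the categorical level for the
#'   enumerated components.
#' @param bands band forms per mm3 (used by `"leukocytes"` only).
#' @param ards logical ARDS flag (used by `"oxygenation"` only).
#' @return integer points in `0:2`.
#' @examples
#' cpis_component_points("temperature", 39.2)                 # 2
#' cpis_component_points("leukocytes", 15000, bands = 600)    # 2
#' cpis_component_points("oxygenation", 200, ards = TRUE)     # 0
#' @export
cpis_component_points <- function(component, value, bands = 0, ards = FALSE) {
  component <- match.arg(component,
    c("temperature", "leukocytes", "oxygenation",
      "secretions", "radiography", "microbiology"))
  switch(component,
    temperature = {
      if (!is.finite(value) || value < 25 || value > 45)
        stop("temperature out of valid domain [25, 45]", call. = FALSE)
      .pts_temperature(value)
    },
    leukocytes = {
      if (!is.finite(value) || value < 0)
        stop("wbc must be non-negative", call. = FALSE)
      if (!is.finite(bands) || bands < 0)
        stop("band forms must be non-negative", call. = FALSE)
      .pts_leukocytes(value, bands)
    },
    oxygenation = {
      if (!is.finite(value) || value <= 0)
        stop("pf_ratio must be positive", call. = FALSE)
      .pts_oxygenation(value, ards)
    },
    secretions = .pts_enum(match.arg(value, .secretions_levels), .secretions_levels),
    radiography = .pts_enum(match.arg(value, .radiography_levels), .radiography_levels),
    microbiology = .pts_enum(match.arg(value, .microbiology_levels), .microbiology_levels)
  )
}

#' Procalcitonin points
#'
#' Bands serum procalcitonin for the PCT-augmented score variants:
#' `< 0.5` ng/mL scores 0, `[0.5, 1)` scores 1, `>= 1` scores 2. A missing
#' PCT yields `NA`, which propagates to every composite that needs it.
#'
#' @param pct procalcitonin in ng/mL (vectorised; `NA` allowed).
#' @return integer points in `0:2`, or `NA` where `pct` is missing.
#' @export
pct_points <- function(pct) {
  if (any(!is.na(pct) & pct < 0))
    stop("pct_points: pct must be non-negative", call. = FALSE)
  ifelse(is.na(pct), NA_integer_,
         ifelse(pct >= 1, 2L, ifelse(pct >= 0.5, 1L, 0L)))
}

# per-finding point maps (vectorised over level strings)
.pts_consolidation <- function(x) c(none = 0L, subpleural = 1L, lobar = 2L)[x]
.pts_size          <- function(x) c(none = 0L, lt15 = 0L, s15to20 = 1L, gt20 = 2L)[x]
.pts_laterality    <- function(x) c(none = 0L, bilateral = 1L, unilateral = 2L)[x]
.pts_bronchogram   <- function(x) c(none = 0L, static = 1L, dynamic = 3L)[x]

#' Lung-ultrasound sub-score
#'
#' Sums the four LUS finding points: consolidation type (none 0 /
#' subpleural 1 / lobar 2), size band (< 15 mm 0 / 15--20 mm 1 / > 20 mm 2),
#' laterality (bilateral 1 / unilateral 2), and air bronchogram (static 1 /
#' dynamic 3). Absent findings contribute 0, so the sub-score ranges over
#' 0--9.
#'
#' @param exam a [lus_exam()].
#' @return list with `subscore` (integer 0--9) and `breakdown` (named
#'   integer vector of per-finding points).
#' @examples
#' lus_points(lus_exam("lobar", "gt20", "unilateral", "dynamic"))$subscore  # 9
#' @export
lus_points <- function(exam) {
  if (!inherits(exam, "lus_exam")) {
    exam <- do.call(lus_exam, as.list(exam))  # re-validate plain lists
  }
  breakdown <- c(
    consolidation_type = unname(.pts_consolidation(exam$consolidation_type)),
    size_band          = unname(.pts_size(exam$size_band)),
    laterality         = unname(.pts_laterality(exam$laterality)),
    bronchogram        = unname(.pts_bronchogram(exam$bronchogram)))
  list(subscore = sum(breakdown), breakdown = breakdown)
}

#' Compute all score variants for one patient
#'
#' Computes the five score variants from a single episode:
#' \describe{
#'   \item{cpis}{six-component Clinical Pulmonary Infection Score, 0--12.}
#'   \item{lus_score}{the LUS sub-score alone, 0--9.}
#'   \item{cpis_lus}{CPIS with the radiography component replaced by the
#'     LUS sub-score, 0--19.}
#'   \item{cpis_pct}{full CPIS plus PCT points, 0--14.}
#'   \item{cpis_plus}{CPIS without radiography, plus PCT points, plus the
#'     LUS sub-score, 0--21.}
#' }
#' Any composite requiring a missing input (radiography, PCT, or a LUS
#' exam) is `NA`; nothing is imputed.
#'
#' @param patient a [patient_record()].
#' @return list of class `"score_panel"`: the five scores plus
#'   `component_breakdown`, a named vector of every component's points.
#' @export
compute_scores <- function(patient) {
  stopifnot(inherits(patient, "patient_record"))
  comp <- c(
    temperature  = unname(.pts_temperature(patient$temperature)),
    leukocytes   = unname(.pts_leukocytes(patient$wbc, patient$band_forms)),
    oxygenation  = unname(.pts_oxygenation(patient$pf_ratio, patient$ards)),
    secretions   = unname(.pts_enum(patient$secretions, .secretions_levels)),
    radiography  = if (is.na(patient$radiography)) NA_integer_ else
                     unname(.pts_enum(patient$radiography, .radiography_levels)),
    microbiology = unname(.pts_enum(patient$microbiology, .microbiology_levels)))
  pctp <- unname(pct_points(patient$pct))
  if (is.null(patient$lus)) {
    lusp <- NA_integer_
    lus_breakdown <- NULL
  } else {
    lp <- lus_points(patient$lus)
    lusp <- lp$subscore
    lus_breakdown <- stats::setNames(lp$breakdown,
                                     paste0("lus_", names(lp$breakdown)))
  }
  clinical5 <- sum(comp[c("temperature", "leukocytes", "oxygenation",
                          "secretions", "microbiology")])
  cpis <- clinical5 + comp["radiography"]  # NA if no radiograph
  panel <- list(
    cpis      = unname(cpis),
    lus_score = lusp,
    cpis_lus  = unname(clinical5 + lusp),
    cpis_pct  = unname(cpis + pctp),
    cpis_plus = unname(clinical5 + pctp + lusp),
    component_breakdown = c(comp, pct = pctp, lus_breakdown))
  structure(panel, class = "score_panel")
}

#' A threshold classification rule
#'
#' A positivity rule for one score variant, e.g. "CPIS-PLUS >= 12" or
#' "CPIS > 6". Rules are data, not code: the defaults in
#' [default_threshold_rules()] can be replaced or extended.
#'
#' @param score_name one of `"cpis"`, `"lus_score"`, `"cpis_lus"`,
#'   `"cpis_pct"`, `"cpis_plus"`.
#' @param cutoff integer cut-off; must be attainable for the score.
#' @param comparison `"ge"` (positive iff score >= cutoff) or `"gt"`.
#' @return list of class `"threshold_rule"`.
#' @export
threshold_rule <- function(score_name, cutoff, comparison = c("ge", "gt")) {
  score_name <- match.arg(score_name, .score_names)
  comparison <- match.arg(comparison)
  ranges <- list(cpis = c(0, 12), lus_score = c(0, 9), cpis_lus = c(0, 19),
                 cpis_pct = c(0, 14), cpis_plus = c(0, 21))
  r <- ranges[[score_name]]
  if (cutoff < r[1] || cutoff > r[2])
    stop(sprintf("threshold_rule: cutoff %s outside attainable range [%d, %d] of %s",
                 cutoff, r[1], r[2], score_name), call. = FALSE)
  structure(list(score_name = score_name, cutoff = as.integer(cutoff),
                 comparison = comparison),
            class = "threshold_rule")
}

#' Default positivity rules for the five score variants
#'
#' CPIS > 6, CPIS-LUS >= 12, CPIS-PLUS >= 12, LUS >= 7, CPIS-PCT >= 7.
#' Note the deliberate strict inequality for CPIS.
#'
#' @return named list of [threshold_rule()]s.
#' @export
default_threshold_rules <- function() {
  list(cpis      = threshold_rule("cpis", 6, "gt"),
       cpis_lus  = threshold_rule("cpis_lus", 12, "ge"),
       cpis_plus = threshold_rule("cpis_plus", 12, "ge"),
       lus_score = threshold_rule("lus_score", 7, "ge"),
       cpis_pct  = threshold_rule("cpis_pct", 7, "ge"))
}

#' Classify a score panel against a threshold rule
#'
#' @param panel a `"score_panel"` from [compute_scores()], or a numeric
#'   vector of score values.
#' @param rule a [threshold_rule()].
#' @return `"positive"`, `"negative"`, or `"undetermined"` (score
#'   undefined); vectorised when `panel` is numeric.
#' @export
classify <- function(panel, rule) {
  stopifnot(inherits(rule, "threshold_rule"))
  score <- if (inherits(panel, "score_panel")) panel[[rule$score_name]] else panel
  pos <- if (rule$comparison == "ge") score >= rule$cutoff else score > rule$cutoff
  ifelse(is.na(score), "undetermined", ifelse(pos, "positive", "negative"))
}

#' Score a whole cohort
#'
#' Vectorised application of [compute_scores()] over a cohort data frame in
#' the cohort CSV schema (see [read_cohort()]), appending the five score
#' columns and, optionally, one prediction column per threshold rule.
#'
#' @param cohort cohort data frame (schema of [read_cohort()]).
#' @param rules optional named list of [threshold_rule()]s; for each a
#'   column `pred_<name>` with values positive/negative/undetermined is
#'   appended.
#' @return the cohort with columns `cpis`, `lus_score`, `cpis_lus`,
#'   `cpis_pct`, `cpis_plus` (integer or `NA`) appended.
#' @export
score_cohort <- function(cohort, rules = NULL) {
  validate_cohort(cohort)
  comp_t <- .pts_temperature(cohort$temperature_c)
  comp_l <- .pts_leukocytes(cohort$wbc_per_mm3, cohort$band_forms_per_mm3)
  comp_o <- .pts_oxygenation(cohort$pf_ratio, cohort$ards == 1)
  comp_s <- .pts_enum(cohort$secretions, .secretions_levels)
  comp_r <- ifelse(is.na(cohort$radiography), NA_integer_,
                   .pts_enum(cohort$radiography, .radiography_levels))
  comp_m <- .pts_enum(cohort$microbiology, .microbiology_levels)
  pctp   <- pct_points(cohort$pct_ng_ml)
  lus_on <- cohort$lus_performed == 1
  lusp <- ifelse(!lus_on, NA_integer_,
                 .pts_consolidation(cohort$consolidation_type) +
                 .pts_size(cohort$size_band) +
                 .pts_laterality(cohort$laterality) +
                 .pts_bronchogram(cohort$bronchogram))
  clinical5 <- comp_t + comp_l + comp_o + comp_s + comp_m
  cohort$cpis      <- as.integer(clinical5 + comp_r)
  cohort$lus_score <- as.integer(lusp)
  cohort$cpis_lus  <- as.integer(clinical5 + lusp)
  cohort$cpis_pct  <- as.integer(clinical5 + comp_r + pctp)
  cohort$cpis_plus <- as.integer(clinical5 + pctp + lusp)
  if (!is.null(rules)) {
    for (nm in names(rules)) {
      rule <- rules[[nm]]
      cohort[[paste0("pred_", nm)]] <- classify(cohort[[rule$score_name]], rule)
    }
  }
  cohort
}
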