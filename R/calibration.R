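# Printed group counts from the pilot PICU cohort (108 suspected-VAP
# episodes; 51 confirmed; LUS performed in 84, of whom 49 VAP / 35 no-VAP)
# that calibrate the synthetic-cohort generator and are reanalysed by the
# derivation pipeline. Counts are VAP vs no-VAP within the LUS subset
# unless noted.

#' Pilot-cohort LUS feature counts
#'
#' Per-level cross-counts of the four lung-ultrasound findings against the
#' confirmed-VAP label in the pilot PICU cohort's LUS subset (n = 84;
#' 49 VAP, 35 no-VAP). Reference categories are "no consolidation" for
#' type, size and laterality, and "no bronchogram" for bronchogram. These
#' counts are the inputs from which the published odds ratios and the
#' derived score points are recomputable.
#'
#' @return data frame with columns `feature`, `level`, `vap`, `no_vap`,
#'   `reference` (logical).
#' @export
pilot_lus_counts <- function() {
  data.frame(
    feature = c(rep("consolidation_type", 3), rep("laterality", 3),
                rep("size_band", 4), rep("bronchogram", 3)),
    level = c("none", "subpleural", "lobar",
              "none", "bilateral", "unilateral",
              "none", "lt15", "s15to20", "gt20",
              "none", "static", "dynamic"),
    vap    = c(1, 1, 47,  1, 7, 41,  1, 1, 8, 39,  1, 10, 38),
    no_vap = c(7, 7, 21,  7, 13, 15,  7, 7, 9, 12,  14, 19, 2),
    reference = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE,
                  TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Pilot-cohort headline counts and distribution summaries
#'
#' Whole-cohort constants of the pilot PICU cohort that calibrate the synthetic
#' generator: episode counts, confirmed-VAP prevalence, LUS coverage,
#' per-group tracheal-secretion counts, fever frequencies, and the
#' median/IQR summaries of procalcitonin (LUS subset, per group) and blood
#' leukocytes (whole cohort).
#'
#' @return nested list of counts and summaries.
#' @export
pilot_cohort_summary <- function() {
  list(
    n_total = 108, n_vap = 51, n_lus = 84, n_lus_vap = 49, n_lus_no_vap = 35,
    secretions = list(                        # absent / non-purulent / purulent
      vap    = c(absent_minimal = 12, non_purulent = 24, purulent = 15),
      no_vap = c(absent_minimal = 32, non_purulent = 23, purulent = 2)),
    fever = list(vap = c(38, 51), no_vap = c(36, 57)),   # events / group size
    pct_quartiles = list(                     # ng/mL: median, q1, q3
      vap    = c(median = 0.47, q1 = 0.17, q3 = 1.32),
      no_vap = c(median = 0.21, q1 = 0.10, q3 = 0.79)),
    wbc_quartiles = c(median = 12400, q1 = 8500, q3 = 16200))
}

#' Contingency tables for every non-reference pilot LUS level
#'
#' Convenience accessor: one [contingency_table()] per non-reference
#' feature level of [pilot_lus_counts()], against that feature's reference
#' level.
#'
#' @return named list of [contingency_table()]s, names `feature:level`.
#' @export
pilot_contingency_tables <- function() {
  counts <- pilot_lus_counts()
  out <- list()
  for (f in unique(counts$feature)) {
    sub <- counts[counts$feature == f, ]
    ref <- sub[sub$reference, ]
    for (i in which(!sub$reference)) {
      nm <- paste(f, sub$level[i], sep = ":")
      out[[nm]] <- contingency_table(a = sub$vap[i], b = sub$no_vap[i],
                                     c = ref$vap, d = ref$no_vap)
    }
  }
  out
}

#' Deterministic cohort matching the pilot marginal counts
#'
#' Reconstructs a 108-episode cohort whose per-feature marginal counts
#' equal the pilot cohort's printed counts exactly: 51 confirmed VAP, LUS
#' performed in 84 (49 VAP / 35 no-VAP), every LUS-finding level count of
#' [pilot_lus_counts()], the per-group tracheal-secretion counts, and the
#' per-group fever frequencies. The joint distribution across features is
#' an arbitrary (deterministic) coupling — the printed tables identify
#' only the margins — so the cohort is synthetic: it supports exact
#' reanalysis of any per-feature statistic, not of joint ones.
#' Procalcitonin is left missing (only its group median/IQR was printed);
#' remaining clinical columns carry neutral filler values.
#'
#' @return cohort data frame in the cohort CSV schema.
#' @export
pilot_like_cohort <- function() {
  cs <- pilot_cohort_summary()
  counts <- pilot_lus_counts()
  cnt <- function(feature, level, col) {
    counts[[col]][counts$feature == feature & counts$level == level]
  }
  build_group <- function(vap, n_lus, n_total) {
    col <- if (vap) "vap" else "no_vap"
    n_none <- cnt("consolidation_type", "none", col)
    n_cons <- n_lus - n_none
    type <- c(rep("none", n_none),
              rep("subpleural", cnt("consolidation_type", "subpleural", col)),
              rep("lobar", cnt("consolidation_type", "lobar", col)))
    # unconsolidated exams carry no size/laterality/bronchogram
    size <- c(rep("none", n_none),
              rep("lt15", cnt("size_band", "lt15", col)),
              rep("s15to20", cnt("size_band", "s15to20", col)),
              rep("gt20", cnt("size_band", "gt20", col)))
    lat <- c(rep("none", n_none),
             rep("bilateral", cnt("laterality", "bilateral", col)),
             rep("unilateral", cnt("laterality", "unilateral", col)))
    bg_none_cons <- cnt("bronchogram", "none", col) - n_none
    bg <- c(rep("none", n_none), rep("none", bg_none_cons),
            rep("static", cnt("bronchogram", "static", col)),
            rep("dynamic", cnt("bronchogram", "dynamic", col)))
    secr <- rep(names(cs$secretions[[col]]), cs$secretions[[col]])
    fever <- cs$fever[[col]]
    temp <- rep(c(39.0, 37.0), c(fever[1], fever[2] - fever[1]))
    data.frame(
      patient_id = NA_character_,
      vap_confirmed = as.integer(vap),
      temperature_c = temp[seq_len(n_total)],
      wbc_per_mm3 = 9000, band_forms_per_mm3 = 0, pf_ratio = 300, ards = 0L,
      secretions = secr[seq_len(n_total)],
      radiography = "no_infiltrate", microbiology = "negative",
      pct_ng_ml = NA_real_,
      lus_performed = rep(c(1L, 0L), c(n_lus, n_total - n_lus)),
      consolidation_type = c(type, rep(NA_character_, n_total - n_lus)),
      size_band = c(size, rep(NA_character_, n_total - n_lus)),
      laterality = c(lat, rep(NA_character_, n_total - n_lus)),
      bronchogram = c(bg, rep(NA_character_, n_total - n_lus)),
      stringsAsFactors = FALSE)
  }
  cohort <- rbind(
    build_group(TRUE, cs$n_lus_vap, cs$n_vap),
    build_group(FALSE, cs$n_lus_no_vap, cs$n_total - cs$n_vap))
  cohort$patient_id <- sprintf("S%03d", seq_len(nrow(cohort)))
  validate_cohort(cohort)
  cohort
}
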