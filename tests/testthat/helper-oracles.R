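# Independent brute-force oracles used across the suite.

# AUC by explicit enumeration of all (positive, negative) pairs.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Two-sided Fisher p by exhaustive enumeration of all 2x2 tables with the
# observed margins under the hypergeometric null: sum the probabilities of
# every table at most as probable as the observed one.
enumerate_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Youden search by trying every observed value as a ">= t" cut-off.
brute_force_youden <- function(scores, labels) {
  best <- list(threshold = NA, j = -Inf)
  n1 <- sum(labels); n0 <- sum(!labels)
  for (t in sort(unique(scores))) {
    sn <- sum(scores >= t & labels) / n1
    sp <- sum(scores < t & !labels) / n0
    j <- sn + sp - 1
    if (j > best$j) best <- list(threshold = t, j = j, sn = sn, sp = sp)
  }
  best
}

# A tiny fully hand-checkable cohort: 6 patients, 4 with LUS.
hand_cohort <- function() {
  data.frame(
    patient_id = paste0("H", 1:6),
    vap_confirmed = c(1L, 1L, 1L, 0L, 0L, 0L),
    temperature_c = c(39.2, 38.7, 37.0, 36.2, 37.5, 38.6),
    wbc_per_mm3 = c(15000, 15000, 9000, 3000, 8000, 12000),
    band_forms_per_mm3 = c(600, 0, 0, 0, 0, 0),
    pf_ratio = c(180, 180, 300, 250, 210, 320),
    ards = c(0L, 0L, 0L, 0L, 1L, 0L),
    secretions = c("purulent", "purulent", "absent_minimal",
                   "non_purulent", "absent_minimal", "absent_minimal"),
    radiography = c("localized", NA, "no_infiltrate", "patchy_diffuse",
                    "no_infiltrate", "no_infiltrate"),
    microbiology = c("positive_with_gram_match", "positive_with_gram_match",
                     "negative", "negative", "positive", "negative"),
    pct_ng_ml = c(2.1, 0.7, 0.3, NA, 0.1, 0.45),
    lus_performed = c(1L, 1L, 0L, 1L, 1L, 0L),
    consolidation_type = c("lobar", "lobar", NA, "subpleural", "none", NA),
    size_band = c("gt20", "gt20", NA, "lt15", "none", NA),
    laterality = c("unilateral", "unilateral", NA, "bilateral", "none", NA),
    bronchogram = c("dynamic", "dynamic", NA, "static", "none", NA),
    stringsAsFactors = FALSE)
}
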