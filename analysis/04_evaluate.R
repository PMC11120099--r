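#!/usr/bin/env Rscript
# Stage 4: diagnostic-accuracy evaluation. Produces the per-rule accuracy
# report (AUC with DeLong intervals; Sn/Sp/PPV/NPV with Wilson intervals
# at the default cut-offs), Youden-optimal cut-offs, all pairwise DeLong
# comparisons, and ROC curve points for plotting.

library(vapscore)

scored <- read_cohort("results/cohort_large_scored.csv")
report <- evaluate_panel(scored)
write_accuracy_report(report, csv = "results/accuracy_report.csv",
                      json = "results/accuracy_report.json")
cat("Accuracy report (n =", nrow(scored), ") -> results/accuracy_report.csv\n")
print(report[, c("score", "cutoff", "auc", "auc_lo", "auc_hi", "sn", "sp",
                 "n_included", "n_excluded")], digits = 3)

cat("\nYouden-optimal cut-offs (score >= t):\n")
for (s in c("cpis", "lus_score", "cpis_lus", "cpis_pct", "cpis_plus")) {
  keep <- !is.na(scored[[s]])
  yt <- youden_threshold(scored[[s]][keep], scored$vap_confirmed[keep] == 1)
  cat(sprintf("  %-10s t=%2d  J=%0.3f (Sn %0.2f, Sp %0.2f)\n",
              s, yt$threshold, yt$j, yt$sn, yt$sp))
}

cat("\nPairwise DeLong comparisons (complete cases per pair):\n")
variants <- c("cpis", "lus_score", "cpis_lus", "cpis_pct", "cpis_plus")
pairs <- utils::combn(variants, 2)
rows <- apply(pairs, 2, function(pr) {
  keep <- !is.na(scored[[pr[1]]]) & !is.na(scored[[pr[2]]])
  cmp <- delong_paired_pvalue(scored[[pr[1]]][keep], scored[[pr[2]]][keep],
                              scored$vap_confirmed[keep] == 1)
  data.frame(score_a = pr[1], score_b = pr[2], auc_a = cmp$auc_a,
             auc_b = cmp$auc_b, z = cmp$z, p_value = cmp$p_value,
             n = cmp$n_used)
})
pairwise <- do.call(rbind, rows)
utils::write.csv(pairwise, "results/delong_pairwise.csv", row.names = FALSE)
print(pairwise, digits = 3)

for (s in variants) {
  keep <- !is.na(scored[[s]])
  rp <- roc_points(scored[[s]][keep], scored$vap_confirmed[keep] == 1)
  utils::write.csv(rp, file.path("results", paste0("roc_", s, ".csv")),
                   row.names = FALSE)
}
cat("\nROC curve points -> results/roc_<score>.csv\n")

# descriptive group comparison, as in the cohort characteristics table
pv <- c(secretions = group_compare(scored, "secretions", "categorical"),
        pct = group_compare(scored, "pct_ng_ml", "continuous_skewed"),
        wbc = group_compare(scored, "wbc_per_mm3", "continuous_skewed"))
cat("\nGroup comparisons (VAP vs no-VAP): ",
    paste(names(pv), signif(pv, 3), sep = " p=", collapse = ", "), "\n")
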