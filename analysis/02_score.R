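#!/usr/bin/env Rscript
# Stage 2: compute the five score variants (CPIS, LUS, CPIS-LUS, CPIS-PCT,
# CPIS-PLUS) for the simulated cohorts and append the default threshold
# classifications. Missing inputs (no LUS exam, no PCT, no radiograph)
# propagate to NA composites; exclusions are reported, never silent.

library(vapscore)

for (stem in c("cohort_pilot_size", "cohort_large")) {
  cohort <- read_cohort(file.path("results", paste0(stem, ".csv")))
  scored <- score_cohort(cohort, rules = default_threshold_rules())
  out <- file.path("results", paste0(stem, "_scored.csv"))
  write_cohort(scored, out)
  vap <- scored$vap_confirmed == 1
  cat(sprintf(
    "%s: n=%d | mean CPIS %0.2f (VAP) vs %0.2f (no-VAP) | %d lack LUS-dependent scores -> %s\n",
    stem, nrow(scored), mean(scored$cpis[vap]), mean(scored$cpis[!vap]),
    sum(is.na(scored$cpis_plus)), out))
}
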