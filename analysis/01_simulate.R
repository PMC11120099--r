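#!/usr/bin/env Rscript
# Stage 1: simulate suspected-VAP cohorts under the default (pilot-
# calibrated) conditions and write them in the cohort CSV dialect.
# Outputs: results/cohort_pilot_size.csv (n = 108, the pilot's size) and
# results/cohort_large.csv (n = 2000, for stable accuracy estimates).

library(vapscore)

dir.create("results", showWarnings = FALSE)
config <- default_generator_config()

cat("Default conditions: prevalence", round(config$prevalence, 3),
    "| LUS coverage", round(config$p_lus_performed, 3), "\n")

small <- generate_cohort(config, n = 108, seed = 20240101)
write_cohort(small, "results/cohort_pilot_size.csv")
cat("n=108 cohort:", sum(small$vap_confirmed), "confirmed VAP,",
    sum(small$lus_performed), "with LUS ->", "results/cohort_pilot_size.csv\n")

large <- generate_cohort(config, n = 2000, seed = 20240102)
write_cohort(large, "results/cohort_large.csv")
cat("n=2000 cohort:", sum(large$vap_confirmed), "confirmed VAP ->",
    "results/cohort_large.csv\n")

# the deterministic reconstruction of the pilot's printed margins, used by
# the derivation stage
write_cohort(pilot_like_cohort(), "results/cohort_pilot_margins.csv")
cat("pilot-margin cohort (108 episodes, synthetic coupling) ->",
    "results/cohort_pilot_margins.csv\n")
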