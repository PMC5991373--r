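#!/usr/bin/env Rscript
# Stage 1: draw the default synthetic pilot cohort (239 respondents in three
# dermatologist-diagnosed classes) and write it in the cohort CSV dialect.
# The generator's parameters encode the published per-class response
# marginals, skip logic and item missingness, so this file stands in for the
# undeposited respondent-level data in every later stage.

suppressPackageStartupMessages(library(altoscreen))
dir.create("results", showWarnings = FALSE)

spec <- default_cohort_spec()
cohort <- generate_cohort(spec)          # spec carries its own default seed
write_cohort(cohort, "results/cohort.csv")

cat("Simulated cohort:", nrow(cohort), "respondents\n")
print(table(cohort$diagnosis))
cat("\nPer-item missing counts (unanswered among administered):\n")
for (q in c("q1", "q2", "q3", "q3a", "q3b", "q4", "q5")) {
  adm <- if (q %in% c("q3a", "q3b")) cohort$q3 == "yes" else rep(TRUE, nrow(cohort))
  cat(sprintf("  %-3s %d\n", q, sum(cohort[[q]][adm] == "missing")))
}
cat(sprintf("  q6  %d\n", sum(q6_missing(cohort$q6))))
cat("\nWrote results/cohort.csv\n")
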