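#!/usr/bin/env Rscript
# Stage 3: survey-item response breakdown by diagnosis class - count and
# percent answering yes per item (pictures: per selection), denominators
# being respondents who answered the item among those it was administered to.

suppressPackageStartupMessages(library(altoscreen))

cohort <- read_cohort("results/cohort.csv")
t2 <- table2_report(cohort)
utils::write.csv(t2, "results/table2.csv", row.names = FALSE)

wide <- stats::reshape(
  transform(t2, cell = sprintf("%d/%d (%.1f)", n_yes, n_answered, pct))[
    , c("item", "class", "cell")],
  idvar = "item", timevar = "class", direction = "wide")
names(wide) <- sub("^cell\\.", "", names(wide))
print(wide, row.names = FALSE)
cat("\nWrote results/table2.csv\n")
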