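#!/usr/bin/env Rscript
# Population-weighted life expectancy with 95% CIs by HOLC grade, by
# gentrification status, and by their cross (transformation status).

suppressPackageStartupMessages(library(gentriflow))

tracts <- read_tracts("results/inputs/tracts.csv")
status <- read.csv("results/tract_status.csv", stringsAsFactors = FALSE)
an <- merge(filter_tracts(tracts)$analysis, status, by = "tract_id")

le <- rbind(
  cbind(grouping = "holc_grade", weighted_le_summary(an, "holc_grade")),
  cbind(grouping = "gentrification_status",
        weighted_le_summary(an, "gentrification_status")),
  cbind(grouping = "transformation_status",
        weighted_le_summary(an, c("holc_grade",
                                  "gentrification_status"))))
write.csv(le, "results/le_by_group.csv", row.names = FALSE)

h <- le[le$grouping == "holc_grade", ]
for (i in seq_len(nrow(h))) {
  message(sprintf("%-22s %5.1f (%.1f to %.1f), %d tracts", h$group[i],
                  h$weighted_mean_le[i], h$ci_low[i], h$ci_high[i],
                  h$n_tracts[i]))
}
message("wrote results/le_by_group.csv")
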