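#!/usr/bin/env Rscript
# Tract exclusion filter plus HOLC grade and gentrification status
# assignment.  Reports the metro composition as counts with one-decimal
# percentages.

suppressPackageStartupMessages(library(gentriflow))

tracts <- read_tracts("results/inputs/tracts.csv")
ft <- filter_tracts(tracts)
status <- tract_status(ft$analysis)
write.csv(status, "results/tract_status.csv", row.names = FALSE)

n <- nrow(status)
for (g in unique(status$holc_grade)) {
  k <- sum(status$holc_grade == g)
  message(sprintf("%-22s %4d (%.1f%%)", g, k, pct_report(k, n)))
}
gentrified <- sum(status$gentrification_status %in% c("earlier", "recent"))
message(sprintf("gentrified (either window): %d (%.1f%%)",
                gentrified, pct_report(gentrified, n)))
red <- status$holc_grade == "hazardous"
redg <- sum(red & status$gentrification_status %in% c("earlier", "recent"))
message(sprintf("redlined tracts gentrified: %d of %d (%.1f%%)",
                redg, sum(red), pct_report(redg, sum(red))))
message("wrote results/tract_status.csv")
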