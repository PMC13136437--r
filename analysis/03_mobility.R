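#!/usr/bin/env Rscript
# Household panel -> per-tract socio-spatial mobility profile: exclusion
# of incomplete records, pooled income quartiles, first/last-location
# mover coding, net changes by income class, and quartile magnitude
# categories.  Summarizes increasing/decreasing tracts by gentrification
# status.

suppressPackageStartupMessages(library(gentriflow))

households <- read_households("results/inputs/households.csv")
status <- read.csv("results/tract_status.csv", stringsAsFactors = FALSE)

mob <- mobility_profile(households, status$tract_id, status = status)
write.csv(mob$profile, "results/mobility_profile.csv", row.names = FALSE)
write.csv(mob$summary, "results/mobility_summary.csv", row.names = FALSE)

message("income class thresholds: Q1 = ",
        round(mob$income_thresholds["q1"]), ", Q3 = ",
        round(mob$income_thresholds["q3"]))
print(table(mob$moves$mover_type, useNA = "ifany"))
rng <- attr(mob$profile, "ranges")
for (k in names(rng)) {
  message("net change in ", k, "-income households, category ranges:")
  for (lv in names(rng[[k]])) {
    message(sprintf("  %-14s %+d to %+d", lv, rng[[k]][[lv]][1],
                    rng[[k]][[lv]][2]))
  }
}
message("wrote results/mobility_profile.csv, results/mobility_summary.csv")
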