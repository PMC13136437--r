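#!/usr/bin/env Rscript
# OLS battery: (i) unadjusted models of life expectancy on each mobility
# magnitude category; (ii) HOLC-stratified models of gentrification
# status, unadjusted and adjusted for the three mobility characteristics,
# plus the non-White-change sensitivity variant.

suppressPackageStartupMessages(library(gentriflow))

tracts <- read_tracts("results/inputs/tracts.csv")
status <- read.csv("results/tract_status.csv", stringsAsFactors = FALSE)
profile <- read.csv("results/mobility_profile.csv",
                    stringsAsFactors = FALSE)

an <- merge(filter_tracts(tracts)$analysis, status, by = "tract_id")
an <- merge(an, profile[, c("tract_id", "cat_lower", "cat_moderate",
                            "cat_higher")], by = "tract_id")
an$pct_non_white_change <- an$pct_non_white_2018 - an$pct_non_white_2011

table1 <- fit_mobility_ols(an)
write.csv(table1, "results/model_table1.csv", row.names = FALSE)

fig2 <- rbind(
  cbind(fit_stratified_ols(an, adjusted = FALSE), variant = "unadjusted"),
  cbind(fit_stratified_ols(an, adjusted = TRUE), variant = "adjusted"),
  cbind(fit_stratified_ols(an, adjusted = TRUE, sensitivity = TRUE),
        variant = "sensitivity"))
write.csv(fig2, "results/model_fig2.csv", row.names = FALSE)

hz <- fig2[fig2$stratum == "hazardous" &
             fig2$term == "gentrification_status" &
             fig2$level == "none", ]
for (i in seq_len(nrow(hz))) {
  message(sprintf(
    "hazardous, none vs earlier (%s): %+.2f (%.2f to %.2f)",
    hz$variant[i], hz$coefficient[i], hz$ci_low[i], hz$ci_high[i]))
}
message("wrote results/model_table1.csv, results/model_fig2.csv")
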