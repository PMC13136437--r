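#!/usr/bin/env Rscript
# Generate the synthetic metropolitan area: a 20x20 tract lattice with
# HOLC grades clustered in the urban core, planted gentrification drift,
# and ~26,000 household traces over 2011-2018.  The lattice is larger
# than the package default so each HOLC stratum comfortably supports the
# adjusted stratified regressions (~40 hazardous tracts vs the 12
# parameters of the adjusted model).  Writes the input tables every later
# step consumes.

suppressPackageStartupMessages(library(gentriflow))

cfg <- metro_config(n_rows = 20, n_cols = 20,
                    n_households_per_tract = 60,
                    le_missing_prob = 0.038)
metro <- generate_metro(cfg)
write_metro(metro, "results/inputs")

message("tracts: ", nrow(metro$tracts),
        "; households: ", length(unique(metro$households$household_id)))
message("planted statuses: ",
        paste(names(table(metro$truth$true_gentrification_status)),
              table(metro$truth$true_gentrification_status),
              collapse = ", "))
message("wrote results/inputs/{tracts,adjacency,households}.csv, ",
        "tracts.geojson, truth.json")
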