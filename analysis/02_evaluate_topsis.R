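#!/usr/bin/env Rscript
# Step 2: comprehensive benefit evaluation.
#
# Runs the TOPSIS evaluation on the herb growth-and-quality matrix and the
# 17-parameter soil-quality matrix from step 1 (soil pH handled as an
# interval criterion with optimum range 7-8), and writes ranking tables in
# the conventional layout: treatment, Di+, Di-, Ci, rank (3 decimals, with
# a full-precision companion file).

suppressPackageStartupMessages(library(cropeval))

herb <- read_decision_matrix("results/herb_matrix.csv",
                             read_indicator_config("results/herb_indicators.yml"))
soil <- read_decision_matrix("results/soil_matrix.csv",
                             read_indicator_config("results/soil_indicators.yml"))

herb_res <- run_topsis(herb)
soil_res <- run_topsis(soil)
write_topsis_report(herb_res, "results/herb_topsis.csv")
write_topsis_report(soil_res, "results/soil_topsis.csv")

message("herb growth-and-quality evaluation:")
print(herb_res)
message("soil quality evaluation:")
print(soil_res)
message(sprintf("best herb system: %s; best soil system: %s",
                herb_res$treatment[herb_res$rank == 1],
                soil_res$treatment[soil_res$rank == 1]))
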