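#!/usr/bin/env Rscript
# Step 1: simulate the trial.
#
# Generates a synthetic two-region, eight-treatment strip-intercropping
# trial (45 replicates for agronomic traits, 4 for metabolite and soil
# traits), derives the composite traits (total biomasses, alkaloid totals,
# C/N ratio), assembles the herb 6-indicator and soil 17-indicator decision
# matrices, and draws sample-by-taxon abundance tables for the three
# Jiangyou soil communities. Everything is written under results/ and read
# by the later steps.

suppressPackageStartupMessages(library(cropeval))

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 42L
dir.create("results", showWarnings = FALSE)

design <- default_trial_design(seed = seed)
trial <- derive_traits(generate_trial(design))
write_trial_data(trial, "results/trial_data.csv")
message(sprintf("simulated %d records over %d treatments (seed %d)",
                nrow(trial), length(unique(trial$treatment)), seed))

herb_ind <- herb_indicator_config()
soil_ind <- soil_indicator_config()
write_indicator_config(herb_ind, "results/herb_indicators.yml")
write_indicator_config(soil_ind, "results/soil_indicators.yml")
write_decision_matrix(generate_indicator_matrix(trial, herb_ind),
                      "results/herb_matrix.csv")
write_decision_matrix(generate_indicator_matrix(trial, soil_ind),
                      "results/soil_matrix.csv")
message("wrote herb (6-indicator) and soil (17-indicator) decision matrices")

# Three soil communities, three replicate samples each: the two intercrop
# communities share an enriched taxon block, the monoculture control leans
# the other way.
n_taxa <- 60
base <- rep(1 / n_taxa, n_taxa)
enrich <- function(idx, f) {
  p <- base
  p[idx] <- p[idx] * f
  p / sum(p)
}
groups <- list("J-maize" = enrich(1:20, 4), "J-rice" = enrich(11:30, 4),
               "J-control" = enrich(41:60, 6))
tabs <- Map(function(nm, p, k) {
  generate_taxon_table(3, n_taxa, concentration = 40, prob = p,
                       seed = seed + k, sample_prefix = paste0(nm, "_"))
}, names(groups), groups, seq_along(groups))
taxa <- do.call(rbind, tabs)
attr(taxa, "seed") <- seed
write_taxon_table(taxa, "results/taxon_table.csv")
message(sprintf("wrote %d x %d taxon table", nrow(taxa), ncol(taxa)))
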