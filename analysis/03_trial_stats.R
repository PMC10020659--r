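#!/usr/bin/env Rscript
# Step 3: treatment-versus-control effect summaries.
#
# Percent increments over each region's monoculture control with Welch
# t-tests and significance stars for every trait, region-average soil-pH
# gains, and a Pearson correlation screen (alpha = 0.05) over the
# treatment-level means of the agronomy/soil variables.

suppressPackageStartupMessages(library(cropeval))

trial <- read_trial_data("results/trial_data.csv")

es <- effect_summaries(trial)
utils::write.csv(es, "results/effect_summaries.csv", row.names = FALSE)
message(sprintf("wrote %d effect summaries (%d starred at p < 0.05)",
                nrow(es), sum(es$stars != "ns")))

for (region in unique(trial$region)) {
  message(sprintf("average soil-pH increment in %s: %.1f%%", region,
                  region_average_increment(trial, "pH", region)))
}

vars <- c("AGB", "FW", "CW", "disease index", "pH", "organic matter",
          "NH4+-N", "NO3--N", "K", "amoA", "invertase", "C/N ratio")
trt_means <- sapply(vars, function(v) {
  sub <- trial[trial$trait == v, ]
  tapply(sub$value, sub$treatment, mean)
})
cs <- correlation_screen(trt_means, alpha = 0.05)
utils::write.csv(data.frame(variable = rownames(cs$masked), cs$masked,
                            check.names = FALSE),
                 "results/correlation_matrix.csv", row.names = FALSE)
utils::write.csv(cs$edges, "results/correlation_edges.csv",
                 row.names = FALSE)
message(sprintf("correlation screen: %d/%d pairs retained at alpha = 0.05",
                sum(cs$edges$retained), nrow(cs$edges)))
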