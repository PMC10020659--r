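#!/usr/bin/env Rscript
# Step 4: community diversity.
#
# Alpha diversity (richness, Shannon, Gini-Simpson, Pielou) per soil sample
# and the Bray-Curtis dissimilarity matrix between samples, from the taxon
# table of step 1.

suppressPackageStartupMessages(library(cropeval))

taxa <- read_taxon_table("results/taxon_table.csv")

alpha <- alpha_diversity(taxa)
utils::write.csv(alpha, "results/alpha_diversity.csv", row.names = FALSE)
message("alpha diversity per sample:")
print(alpha, digits = 4)

bc <- bray_curtis(taxa)
utils::write.csv(data.frame(sample = rownames(bc), bc, check.names = FALSE),
                 "results/bray_curtis.csv", row.names = FALSE)
grp <- sub("_[0-9]+$", "", rownames(bc))
same <- outer(grp, grp, "==") & upper.tri(bc)
diff_ <- outer(grp, grp, "!=") & upper.tri(bc)
message(sprintf("mean Bray-Curtis: %.3f within groups, %.3f between groups",
                mean(bc[same]), mean(bc[diff_])))
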