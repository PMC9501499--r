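#!/usr/bin/env Rscript
# Stage 3: diversity. Alpha diversity on counts rarefied to 1763 reads;
# Bray-Curtis + PCoA and a diet/compartment PERMANOVA on the corrected
# relative abundances of the terminal samples.

library(qmpguilds)

seed <- 20220901
set.seed(seed)

study <- read_study("results/study/counts.tsv",
                    "results/study/metadata.tsv",
                    "results/study/copy_numbers.tsv")
study <- filter_min_reads(study, 1000)

deep <- library_sizes(study) >= 1763
alpha <- alpha_diversity(study$counts[deep, ], depth = 1763)
alpha <- merge(alpha, study$metadata[, c("sample_id", "diet", "day",
                                         "compartment")], sort = FALSE)
qmpguilds:::write_tsv(alpha, "results/diversity.tsv",
                      paste("seed:", seed))

a7 <- subset(alpha, day == 7 & compartment == "cecum")
message("cecum day-7 alpha diversity (rarefied to 1763):")
for (d in c("CD", "FFD")) {
  s <- subset(a7, diet == d)
  message(sprintf(
    "  %-4s observed %.1f  shannon %.2f  gini-simpson %.3f",
    d, mean(s$observed_richness), mean(s$shannon), mean(s$simpson)))
}

profile <- qmp_profile(study)
md <- profile$metadata
term <- which(md$compartment != "feces" & md$day == 7)
d <- bray_curtis_matrix(profile$rel_corrected[term, ])
ord <- pcoa_ordination(d)
ord_df <- data.frame(sample_id = md$sample_id[term],
                     PCo1 = ord$coordinates[, 1],
                     PCo2 = ord$coordinates[, 2])
qmpguilds:::write_tsv(ord_df, "results/ordination.tsv",
                      paste("seed:", seed))
message(sprintf("PCoA axes 1-2 explain %.0f%% + %.0f%% of the variation",
                100 * ord$proportion_explained[1],
                100 * ord$proportion_explained[2]))

pm <- permanova(d, md[term, c("diet", "compartment")],
                n_permutations = 999)
qmpguilds:::write_tsv(pm, "results/permanova.tsv", paste("seed:", seed))
message(sprintf("PERMANOVA: diet R2 = %.2f (p = %.3g)",
                pm$R2[1], pm$p_value[1]))
message("wrote results/diversity.tsv, ordination.tsv, permanova.tsv")
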