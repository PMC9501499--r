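#!/usr/bin/env Rscript
# Stage 2: quantitative microbiome profiling.
#
# Reads the study TSVs, drops libraries under 1000 reads, corrects for
# 16S copy numbers, scales by flow-cytometry densities to absolute
# abundance per gram, and by content wet weight to cells per
# compartment.

library(qmpguilds)

study <- read_study("results/study/counts.tsv",
                    "results/study/metadata.tsv",
                    "results/study/copy_numbers.tsv")
study <- filter_min_reads(study, 1000)
profile <- qmp_profile(study)
write_abundance(profile, "results/absolute_abundance.tsv",
                header = "stage: qmp_profile")

md <- profile$metadata
term <- md$compartment != "feces"
load <- sample_load(profile)[term]
agg <- aggregate(load,
                 by = list(diet = md$diet[term],
                           compartment = md$compartment[term]), mean)
message("mean total load per compartment (cells):")
for (i in seq_len(nrow(agg))) {
  message(sprintf("  %-16s %-4s %.3g", agg$compartment[i], agg$diet[i],
                  agg$x[i]))
}
ratio <- with(reshape(agg, idvar = "compartment", timevar = "diet",
                      direction = "wide"), x.FFD / x.CD)
message(sprintf("observed FFD/CD load ratios: %s",
                paste(sprintf("%.2f", ratio), collapse = ", ")))
message("wrote results/absolute_abundance.tsv")
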