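#!/usr/bin/env Rscript
# Stage 6: sample ordination of the simulated cohort.
#
# Classical MDS on leading log-fold-change distances (top 500 miRNAs per
# sample pair), with group separation quantified by the mean silhouette
# width of the study groups on the first two axes.

suppressMessages(library(evmirpanel))

counts <- read_count_matrix("results/sim/counts.tsv")
samples <- read_sample_sheet("results/sim/samples.csv", counts = counts)

mds <- mds_coordinates(counts, tmm_factors(counts), top_n = 500)
coords <- data.frame(sample_id = rownames(mds$coords), mds$coords,
                     group = samples$group[match(rownames(mds$coords),
                                                 samples$sample_id)])
write_results_tsv(coords, "results/mds_coordinates.tsv")

sil <- cluster::silhouette(as.integer(factor(coords$group)),
                           dist(mds$coords))
cat(sprintf("MDS: var explained %.1f%% / %.1f%%, stress %.3f\n",
            100 * mds$var_explained[1], 100 * mds$var_explained[2],
            mds$stress))
cat(sprintf("Mean silhouette width over the four groups: %.2f\n",
            mean(sil[, "sil_width"])))
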