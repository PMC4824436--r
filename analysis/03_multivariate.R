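#!/usr/bin/env Rscript
# Unsupervised views of the normalized table: autoscaled PCA of the samples
# and Spearman/average-linkage hierarchical clustering of samples and
# metabolites.

library(metabodose)

gm <- utils::read.csv("results/genotype_map.csv")
tab <- read_abundance_table("results/normalized_abundance.csv", gm)

pca <- run_pca(tab, scaling = "autoscale")
cat(sprintf("PC1 explains %.1f%%, PC2 %.1f%% of total variance\n",
            100 * pca$variance_fraction[1], 100 * pca$variance_fraction[2]))
utils::write.table(
  data.frame(sample = rownames(pca$scores), genotype = pca$genotypes,
             pca$scores[, 1:3], check.names = FALSE),
  "results/pca_scores.tsv", sep = "\t", row.names = FALSE, quote = FALSE)

cent <- tapply(pca$scores[, 1], tab$genotypes, mean)
cat("PC1 genotype centroids:\n"); print(round(cent, 2))

hc_s <- cluster_hca(tab, "samples")
write_dendrogram_newick(hc_s, "results/hca_samples.nwk")
hc_m <- cluster_hca(tab, "metabolites")
write_dendrogram_newick(hc_m, "results/hca_metabolites.nwk")
cat("wrote sample and metabolite dendrograms (Newick)\n")
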