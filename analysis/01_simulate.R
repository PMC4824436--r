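#!/usr/bin/env Rscript
# Generate the synthetic study-design dataset: 5 genotypes (WT, het, hom,
# rescue, gal4) x 6 replicates x 109 metabolites with planted dosage,
# consensus and marker effects under multiplicative lognormal noise
# (cv = 0.2), plus light residual missingness (2%: the reported panel has
# already passed the upstream detection filter, so only occasional cells
# are absent) to exercise the presence filter and imputation. Writes the
# raw table, the genotype map and the ground truth under results/.

library(metabodose)

dir.create("results", showWarnings = FALSE)
cfg <- sim_config(missing_rate = 0.02, seed = 20160407)
gen <- generate_abundance(cfg)

write_abundance_table(gen$table, "results/synthetic_abundance.csv")
utils::write.csv(data.frame(sample = gen$table$sample_ids,
                            genotype = gen$table$genotypes),
                 "results/genotype_map.csv", row.names = FALSE)
write_truth(gen$truth, "results/truth.json")

cat("generated", nrow(gen$table$values), "samples x",
    ncol(gen$table$values), "metabolites;",
    sum(is.na(gen$table$values)), "missing cells\n")
cat("planted:", sum(gen$truth$class == "dosage_down"), "dosage-down,",
    sum(gen$truth$class == "dosage_up"), "dosage-up,",
    sum(grepl("consensus", gen$truth$class)), "consensus,",
    sum(gen$truth$class == "marker"), "marker\n")
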