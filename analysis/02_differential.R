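#!/usr/bin/env Rscript
# Presence-filter (80% per group), impute (half-minimum), mTIC-normalize,
# then run the pooled-variance Student's t-test differential comparison of
# the homozygous mutant against wild type, and summarize the P < 0.05
# filter counts and fold-change extremes.

library(metabodose)

gm <- utils::read.csv("results/genotype_map.csv")
tab <- read_abundance_table("results/synthetic_abundance.csv", gm)
tab <- normalize_tic(impute_missing(presence_filter(tab, 0.8)))
write_abundance_table(tab, "results/normalized_abundance.csv")

res <- compare_groups(tab, test = "hom", reference = "WT", alpha = 0.05)
utils::write.table(res, "results/differential_hom_vs_wt.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

counts <- summarize_filter(res)
cat(sprintf("significant at P<0.05: %d of %d (%d up, %d down)\n",
            counts$n_sig, nrow(res), counts$n_up, counts$n_down))
ex <- rank_extremes(res, n_top = 3)
cat("largest fold changes:\n")
print(ex$top_fold_change)
cat("smallest p-values:\n")
print(ex$top_p)

truth <- jsonlite::read_json("results/truth.json", simplifyVector = TRUE)
planted <- truth$metabolite[truth$class != "null"]
cat(sprintf("planted effects recovered: %d of %d\n",
            sum(res$significant & res$metabolite %in% planted),
            length(planted)))
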