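#!/usr/bin/env Rscript
# Pavlidis template matching for gene-dosage trends across WT -> het -> hom:
# monotone-up and monotone-down linear dosage templates at P < 0.05, with
# the matched clusters compared against the planted truth.

library(metabodose)

gm <- utils::read.csv("results/genotype_map.csv")
tab <- read_abundance_table("results/normalized_abundance.csv", gm)
ord <- c("WT", "het", "hom")

m_up <- match_template(tab, ord, template = c(0, 0.5, 1), threshold = 0.05)
m_down <- match_template(tab, ord, template = c(1, 0.5, 0), threshold = 0.05)
rep_out <- dosage_report(m_up, m_down)
jsonlite::write_json(rep_out, "results/dosage_clusters.json",
                     dataframe = "rows", auto_unbox = TRUE, digits = NA)

cat(sprintf("dosage-up cluster: %d members; dosage-down: %d members\n",
            rep_out$n_up, rep_out$n_down))
truth <- jsonlite::read_json("results/truth.json", simplifyVector = TRUE)
cat(sprintf("planted up recovered: %d/%d; planted down recovered: %d/%d\n",
            sum(truth$metabolite[truth$class == "dosage_up"] %in%
                  rep_out$dosage_up$metabolite),
            sum(truth$class == "dosage_up"),
            sum(truth$metabolite[truth$class == "dosage_down"] %in%
                  rep_out$dosage_down$metabolite),
            sum(truth$class == "dosage_down")))
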