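Package: metabodose
Title: Gene-Dosage Metabolomics: Differential Abundance, Template
    Matching and Two-Layer Metabolic Networks for GC-TOF-MS Profiles
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete analysis pipeline for genotype-series GC-TOF-MS
    metabolite profiling studies. Provides presence filtering, total ion
    chromatogram (mTIC) normalization, half-minimum imputation, pooled
    variance Student's t-test differential abundance with fold changes,
    principal component analysis, Spearman/average-linkage hierarchical
    clustering, Pavlidis template matching against monotone gene-dosage
    templates, two-layer metabolic network reconstruction (Tanimoto
    chemical similarity plus enzymatic reaction pairs) with differential
    node styling, and cross-genotype consensus calling with allele
    discordance checks. Ships a synthetic-data generator that plants
    dosage-dependent, consensus and marker effects under multiplicative
    lognormal noise so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB
Config/testthat/edition: 3
RoxygenNote: 7.3.3
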