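---
title: "Methods: gene-dosage metabolomics with metabodose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-dosage metabolomics with metabodose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabodose)
```

`metabodose` analyses genotype-series GC-TOF-MS metabolite panels: a
samples × metabolites matrix of ion intensities with one genotype label per
sample, typically wild type (two functional gene copies), heterozygote
(one), homozygous null (zero), a second null allele carrying a GAL4
driver, and a rescue strain re-expressing the gene in the null background.
This vignette explains the statistical procedures, the tunable parameters,
the synthetic test bed, and the numerical choices made where the design
was genuinely open.

## Preprocessing

**Presence filter.** A metabolite is reported only when detected in at
least `min_fraction` (default 0.8) of the samples of *every* study group
(study group = genotype). Filtering precedes every statistic. The order
relative to normalization is a genuine choice; we filter first so that
per-sample totals are computed over the same metabolite panel for all
samples, which is what makes the totals comparable.

**Imputation.** Residual missing cells (≤ 20% per group after the filter)
are replaced by half the minimum observed value of that metabolite across
all samples — the standard left-censoring surrogate for
below-detection-limit values in metabolomics. Applied after filtering and
before normalization.

**mTIC normalization.** Each sample is divided by its summed signal over
all identified metabolites, removing per-sample loading and instrument
drift, then multiplied by the cohort mean of the per-sample totals so
values keep their original magnitude (`rescale = "none"` keeps pure
fractions). After normalization every sample total is identical to within
1e-9 relative tolerance. Two properties matter: sample-specific rescaling
(drift) is removed exactly, and within-sample ratios between metabolites
are untouched. Note the method's standing assumption: the summed signal
must not be dominated by one or two compounds, otherwise a genuine change
in a dominant compound leaks into every other metabolite's normalized
value.

## Differential abundance

Per metabolite, a two-sided pooled-variance Student's t-test between the
test and reference genotypes (≥ 2 replicates each), with fold change the
ratio of arithmetic group means, test over reference — so fold change > 1
is "up in the test group". The pooled (classic) form is the default
because it is what "Student's t-test" names; Welch's form is available via
`welch = TRUE`. Significance uses raw p-values at `alpha = 0.05` with no
multiple-testing correction — the convention of the replicated analysis —
but a Benjamini–Hochberg column is emitted for modern reuse. Degenerate
input (both groups constant and equal) yields p = 1 by convention; a zero
reference mean is an error rather than an infinite fold change.

## Multivariate views

**PCA** via singular value decomposition after autoscaling (centre, unit
variance per metabolite; the default for panels spanning orders of
magnitude) or plain centring (`scaling = "center"`, covariance PCA). Signs
are fixed deterministically: within each component the largest-magnitude
loading is made positive. Zero-variance metabolites are an error under
autoscaling, named in the message.

**Hierarchical clustering** uses d = 1 − Spearman rank correlation
(midranks for ties) and average (UPGMA) linkage. Spearman makes the
dendrogram invariant to any monotone transform of the intensities;
constant profiles (undefined rank correlation) are an error naming the
offending item. Trees export as Newick with merge heights as branch
lengths.

## Gene-dosage template matching

Pavlidis template matching scores each metabolite against a template
vector over an ordered genotype series, by default the linear dosage
templates (1, 0.5, 0) for a monotone decrease and (0, 0.5, 1) for a
monotone increase across WT → het → hom. The correlation is computed at
replicate level (template value broadcast to each replicate of its
genotype), giving the significance test n−2 degrees of freedom over all
replicates — the behaviour of the template-matching tools used in
expression analysis; `level = "means"` collapses to per-genotype means
(with only k−2 df, far more conservative). A metabolite is *matched* only
when r > 0 and p < `threshold` (default 0.05); anti-correlated profiles
belong to the mirrored template, so the up and down clusters are mutually
exclusive by construction. Constant profiles are reported unmatched with a
`degenerate` flag, never as NaN.

## Two-layer metabolic network

Chemical-similarity edges connect metabolite pairs whose binary
substructure fingerprints have Tanimoto coefficient |a∩b|/|a∪b| at or
above 0.7, the conventional cut-off for substructure fingerprints.
Precomputed fingerprints (hex-encoded, uniform bit length) are the
canonical input: server-side structure-clustering fingerprints cannot be
regenerated offline bit-for-bit, so shipping the bits keeps the edge set
reproducible; the packaged demonstration annotations carry Morgan
(radius-2, 1024-bit) fingerprints computed from SMILES. Rows with only
SMILES are fingerprinted through the optional ChemmineOB backend, with the
provenance recorded — edge sets depend on the fingerprint scheme, so mixed
provenance should be avoided within one cohort. The biochemical layer is a
plain edge list of substrate–product pairs connected by one enzymatic
reaction, curated by the user (e.g. from KEGG reactant-pair data); the
package never calls a remote database. A pair may carry both layer tags,
kept as two parallel typed edges (the Cytoscape convention). Node styling
encodes the differential result: size affine in |log2 fold change| clipped
at 5 log2 units, colour red/blue for significant up/down and absent
otherwise. Exports: SIF + node-attribute TSV, and GraphML with all
attributes inline; both round-trip through the package's readers.

## Cross-genotype consensus

The **allele-discordance** check compares the two null alleles head to
head: the fraction of the panel significantly different between them is
reported to one decimal, and flagged "within systematic error" when it
does not exceed 100·alpha % — the false-positive rate the test itself
would produce on equivalent groups. **Allele-specific sets** partition the
significant sets of the two null-vs-WT comparisons into unique and shared
parts. The **consensus call** requires a metabolite to be significant in
both the null-vs-WT and the driver-vs-rescue comparisons *with the same
direction*, both oriented so the gene-deficient condition is the test
group ("up" always means up-in-deficiency); unoriented comparisons are
refused, since direction consistency is meaningless without orientation.
Output is ordered by combined evidence (sum of −log10 p), a plumbing
choice for stable output, with ties broken by name.

## The synthetic test bed

`sim_config()` / `generate_abundance()` emulate the study design: 5
genotypes × 6 replicates × 109 metabolites. Baselines are lognormal
(log-mean 10, log-sd 1.0, arbitrary ion counts): right-skewed intensities
spanning two to three orders of magnitude, while keeping the
identified-compound total spread across the panel — the regime in which
mTIC normalization is valid. Planted classes, pairwise disjoint:

- **dosage** (defaults: 17 down, 9 up, |log2 effect| = 1): monotone across
  WT → het → hom with the heterozygote at half the homozygote effect on
  the log2 scale (linear in gene dosage; the simplest monotone choice).
- **consensus** (default 3: two down, one up): the same log2 effect in
  both deficient backgrounds (hom and gal4), rescue restored exactly to
  the wild-type mean.
- **marker** (default one metabolite, +4.7 log2 ≈ 26-fold in every
  non-wild-type genotype): emulates the eye-pigment artifact of
  marker-insertion strains. Its baseline is pinned at a trace level
  (exp(log-mean − 2·log-sd)) because the real artifact is a minor
  by-product; a dominant-abundance marker would violate the mTIC
  assumption above.

Noise is multiplicative lognormal with coefficient of variation `cv`
(default 0.2) on the natural scale, mean-preserving (the expected value of
each cell equals its true group mean; `cv = 0` returns the truth exactly).
Optional missingness masks cells completely at random. The ground truth
(class, log2 effect, per-genotype true means) is emitted as a sidecar so
tests never reach into generator internals.

What the generator does *not* emulate: correlated metabolite modules,
heteroscedastic or intensity-dependent noise, batch/run-order drift,
non-random (intensity-dependent) missingness, and biological coupling
between the planted classes (the dosage class is planted only in the
WT/het/hom allelic series, so the two null alleles genuinely differ in the
test bed — unlike near-equivalent real alleles). Passing recovery tests on
this bed therefore demonstrates the correctness of the statistical
machinery under the declared model, not performance on real data.

## Validation set-up and problem sizes

The test suite validates each numerical path against an independent
oracle: Tanimoto against literal set arithmetic, average-linkage merges
against a naive O(n³) agglomerator, the t-test against the longhand
pooled-variance formula (1000 random 6 vs 6 draws), and PCA variance
fractions against the covariance eigendecomposition. Recovery experiments
use the study design itself: 20 seeds for differential power (planted
|log2| ≥ 1 at cv = 0.2), 10 × 109 fully null metabolite-tests for the
type-I rate, and 20 seeds each for the template-matching and consensus
recoveries. Template-matching recovery is scored by per-metabolite
majority vote across seeds (every planted metabolite matched in a
majority of seeds, no null metabolite matched in a majority): with 83
null metabolites and a per-null false-match probability of about 0.01 at
the P < 0.01 threshold, some seed-level false match is expected in
roughly half of all seeds even for a perfect method, so a per-seed
zero-false criterion would be a coin flip rather than a test; the
majority vote measures the same recovery property stably. Consensus
recovery, whose per-seed false-call probability is tiny (two independent
significance events plus direction agreement), is scored per seed.

## Known limitations

- Normalization leakage: after mTIC normalization, a genuine change in
  abundant compounds alters every metabolite's relative value; "null in
  absolute abundance" and "null in relative abundance" differ. The type-I
  rate is therefore measured on fully null simulations.
- The published PCA variance fractions and allele-specific set sizes
  depend on the raw study data, which is not deposited; the pipeline
  reproduces the published *procedures* and the printed differential
  table, and validates recovery on the synthetic bed instead.
- Reaction-pair edges are only as good as the curated list supplied; the
  packaged list is a small demonstration covering methionine-salvage, TCA
  and serine/glycine chemistry.
- Tanimoto similarity depends on the fingerprint scheme; edge sets from
  different schemes are not comparable.
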