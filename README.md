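# ervregnet

Analysis toolkit for endogenous retrovirus (ERV) subfamilies that act as
shared enhancers of primordial germ cell-like cells (PGCLCs) and naive
pluripotent stem cells — the regulatory signature exemplified by the
hominoid HERVK LTR subfamily LTR5_Hs. The package is aimed at
computational biologists who have standard upstream outputs in hand
(count matrices, peak sets, repeat annotations, locus trees, WGS
alignments) and need the bespoke statistics that connect them.

## What it computes

**Cell-type specificity score.** For each gene or TE subfamily, raw
counts are normalised to CP10k, log-transformed, z-scored across cells,
averaged per cell type and min-max rescaled to [0, 1]; the score is
−log10 of the sum of squared residuals (SSR) between this profile *d* and
a declared model *m* (default germline model
iPSC:iMeLC:PGCLC:MLC:TC:T1LC = 0:0:1:0.5:0:0):

    score = −log10 Σ_c (d_c − m_c)²

A perfect match scores 12.0 under the 1e-12 SSR floor.

**Expression classification.** Features are `both` / `pgclc_only` /
`naive_only` / `other` by crossing the top-10% specificity rule with a
naive-vs-primed differential call (log2FC > 1, FDR < 0.05); a
cross-species comparison then yields the genes *likely regulated* by the
subfamily (shared-up in the focal species, not in the other, adjacent to
an active locus).

**Interval statistics.** A genomic permutation test (length-preserving
uniform shuffles; Poisson upper-tail p at the permutation mean λ), a
GREAT-style binomial test on merged ±50 kb TSS windows
(fold = (Ci/Cb)/(Li/Lb)), Fisher 2×2 category enrichment with
cross-product odds ratios, active-locus definition (> 0.5% detection or
peak overlap), gene adjacency with sensitivity sweeps, and TF regulator
calling (log2 fold enrichment > 2, FDR < 0.05, > 20 events, plus
expression criteria).

**Insertion dating.** MSA/tree filtering rules (85% site coverage, 15%
sequence gaps, z > 3 branch outliers) and a 10-locus sliding window over
tree-ordered loci that assigns each insertion a primate branch (HCGOG,
HCGO, HCG, HC, H) from ortholog presence/absence, then stratifies genes
by the insertion date of their associated loci.

**Polymorphism calling.** Split-read detection of reference TE insertions
absent from individuals: primary soft-clipped reads with `SA` descriptors
whose two segments flank an annotated element within 25 nt of both ends;
two or more such reads call an absent allele.

**Synthetic data.** Generators for every input — cell-labelled count
matrices with planted truth classes, genomes with exact planted
peak–TE overlap, ortholog staircases with planted branches and missing
values, SAM cohorts with planted absent alleles — so every stage is
testable end to end with known ground truth.

## Worked example

```r
library(ervregnet)

sim <- simulate_expression(expression_design(seed = 2))
sc  <- specificity_score(sim$matrix)
head(sc[order(-sc$score), ], 3)
#>           feature          SSR    score
#> gene0083 gene0083 0.0009920254 3.003477
#> gene0116 gene0116 0.0010352298 2.984963
#> gene0170 gene0170 0.0011886677 2.924940

meta <- sim$matrix$cell_meta
de  <- differential_upregulation(sim$matrix,
         meta$cell_id[meta$cell_type == "naiveESC"],
         meta$cell_id[meta$cell_type == "primedESC"])
lab <- classify_features(sc, de)
table(lab$category)
#>       both pgclc_only naive_only      other
#>        100         99        100       1700

gen <- simulate_genome(genome_design(seed = 3))
permutation_enrichment(gen$peaks$atac, gen$te_loci,
                       gen$chrom_lengths, seed = 5)[, 1:6]
#>     query observed lambda fold        p     FDR
#> 1 LTR5_Hs       24   1.36 17.6 7.01e-22 1.4e-21
#> 2   LTR5B        0   0.96  0.0 1.00e+00 1.0e+00
```

The top-scoring genes are planted PGCLC-specific genes (scores near 3
mean SSR ≈ 0.001, an almost exact match to the germline model); the
classifier recovers 100/100 planted shared-up genes and labels no null
gene as upregulated. The permutation test finds the 24 peaks planted on
LTR5_Hs loci against a random expectation of 1.36 (17.6-fold,
Poisson p ≈ 7e-22) and correctly reports no enrichment on the
control subfamily.

The full pipeline — scoring, classification, enrichment, regulator
calling, adjacency, cross-species comparison, dating, polymorphism
calling, gene-set analysis — runs from one seeded configuration:

```r
report <- run_all(default_config(seed = 1, output_dir = "ervrun"))
```

writing one TSV per stage plus `summary.json`; reruns with the same seed
are byte-identical.

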