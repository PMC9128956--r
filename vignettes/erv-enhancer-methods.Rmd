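---
title: "Methods: scoring, enrichment, dating and polymorphism calling for ERV enhancer analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, enrichment, dating and polymorphism calling for ERV enhancer analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervregnet)
```

# Scope

`ervregnet` implements the computational backbone of a comparative
regulatory-genomics study of endogenous retroviruses (ERVs) that behave as
shared enhancers of primordial germ cell-like cells (PGCLCs) and naive
pluripotent stem cells. The youngest human HERVK long terminal repeat
subfamily, LTR5_Hs, is the motivating case: its loci are transcribed and
epigenetically active in both cell states, sit near genes upregulated in
both, and expanded recently enough that insertions can be dated against
the primate tree and are still polymorphic in human populations.

The package covers six analysis stages plus a synthetic-data module:

1. cell-type specificity scoring of genes and TE subfamilies,
2. four-way classification of features by shared/specific upregulation,
3. interval enrichment statistics (genomic permutation, proximity-based
   binomial, Fisher 2x2) and regulator calling,
4. definition of active loci and gene adjacency,
5. phylogeny-guided dating of insertions from ortholog presence/absence,
6. split-read detection of insertionally polymorphic loci.

Sequence alignment, peak calling, count-matrix construction and
tree inference are deliberately out of scope; the package consumes their
outputs (count matrices, BED/narrowPeak intervals, FASTA alignments,
Newick trees, SAM alignments) through standard Bioconductor readers.

# The specificity score

For each feature the raw counts are normalised per cell to counts per
10,000 (CP10k) and transformed to `log2(CP10k + 1)`. Within the scored
cells the feature is standardised to a Z score (population SD, all cells
pooled), the mean Z per cell type is taken, and the per-type means are
min-max rescaled to $[0,1]$, giving the data vector $d$. Against a
declared model vector $m$ the score is

$$\mathrm{score} = -\log_{10} \underbrace{\sum_c (d_c - m_c)^2}_{\mathrm{SSR}}$$

The default model is the germline profile
iPSC:iMeLC:PGCLC:MLC:TC:T1LC = 0:0:1:0.5:0:0 — PGCLC-specific expression
with residual expression in MLCs, where key PGC transcription factors
stay weakly expressed.

Numerical choices:

* **SSR floor.** The SSR is floored at $10^{-12}$, so a feature matching
  the model exactly scores 12.0 rather than infinity; ranks are
  unaffected because no attainable SSR on rescaled data is below the
  floor except exact zero.
* **Zero-variance features** (no variation in relative expression) and
  **degenerate profiles** (all per-type means equal, so the rescale is
  undefined) are excluded and reported in the `skipped` attribute rather
  than erroring: both arise routinely in sparse TE locus matrices.
* The Z score uses the population SD (`ddof = 0`) over all cells of the
  dataset being scored; when several datasets are analysed, each is
  scored separately rather than z-scored jointly, since the score is a
  within-dataset quantity and joint standardisation would couple it to
  dataset composition.

The score is invariant to per-cell sequencing depth (CP10k) and to
feature-wise affine transforms of log expression (Z score); both
invariances are asserted in the test suite, and the whole pipeline is
checked to $10^{-9}$ against a loop-written brute-force reimplementation.

# Classification and cross-species comparison

Features are classified by two orthogonal calls. "Up in PGCLCs" is the
top 10% of the specificity score over the scored universe (ties at the
cutoff are included and the realised fraction is reported — dropping ties
would make the set depend on sort order). "Up in naive cells" is
log2FC > 1 and FDR < 0.05 in the naive-vs-primed differential test. The
cross of the two calls yields `both`, `pgclc_only`, `naive_only`,
`other`. The same rule is reused verbatim for open-chromatin peaks. The
top fraction is computed over the scored universe, i.e. after removal of
unscoreable features; including them would make "10%" depend on how many
features happened to be degenerate.

The bundled differential test is deliberately simple: features are first
filtered on expression (90th percentile of reads-per-million >= 0.2), the
fold change is the ratio of group means of CP10k with a pseudocount of
one, the p-value a Wilcoxon rank-sum test, and the FDR Benjamini-
Hochberg. It is a stand-in for a count-model Wald test; `de_adapter()`
accepts an externally computed table verbatim and the pipeline's
downstream stages are identical in either mode (asserted by a
stage-equivalence test). Manual label overrides (the analyst judging a
borderline gene) are supported as an explicit list, never inferred.

A gene is "likely regulated" by the TE subfamily when it is `both` in the
focal species, its one-to-one ortholog is not `both` in the comparison
species, and it lies within the adjacency distance of an active locus.

# Interval statistics

**Genomic permutation test.** Query regions are relocated uniformly
across the genome, length-preserving, with the destination chromosome
drawn proportional to the number of valid start positions; shuffled
regions may overlap each other and no exclusion regions are applied
(matching the defaults of the shuffling tool the procedure emulates).
Per shuffle, the number of regions overlapping (>= 1 bp, strand-agnostic)
any target locus is counted; the mean over 100 shuffles is the
expectation $\lambda$, fold enrichment is observed/$\lambda$, and the
p-value is the Poisson upper tail $P(X \ge \mathrm{obs})$ at rate
$\lambda$. When $\lambda = 0$ it is floored at $1/n_\mathrm{perm}$ (the
resolution of the permutation estimate) and flagged. Regions — not base
pairs — are counted, consistent with region-level peak enrichment.

**Proximity (GREAT-style) binomial test.** Windows of ±50 kb around the
TSSs of the genes of interest and of the background genes are merged
within each set; the merged lengths $L_i \le L_b$ and the peak counts
$C_i \le C_b$ (a peak counts once per set) give fold
$= (C_i/C_b)/(L_i/L_b)$ and $p = P(X \ge C_i \mid n = C_b, p = L_i/L_b)$.
A window of zero, or an empty interest set, produces an `NA` fold with a
warning rather than an error, because sensitivity sweeps legitimately
visit degenerate corners.

**Fisher 2x2 enrichment.** For category-vs-site-set tables the reported
odds ratio is the cross-product $ad/bc$ (7.0 for the table
[[10,10],[10,70]]), not the conditional MLE, because the cross-product is
what the downstream odds-ratio ranking and thresholds refer to; p-values
come from the exact test, two-tailed for TF/category enrichment.
One-tailed (enrichment-only) testing is reserved for gene-set analysis,
where depletion is not of interest.

**Regulator calling.** A TF is a candidate regulator when its binding
sites are enriched on the subfamily (log2 fold > 2, FDR < 0.05 across
TFs, > 20 binding events) and the TF itself is upregulated in the
relevant state (top-10% specificity score with mean log2(CP10k+1) > 0.4
in PGCLCs; or log2FC > 2, FDR < 0.05, mean > 0.4 in naive cells). The
binding-event floor guards against spuriously large folds from tiny site
sets.

**Adjacency.** Distance between a TSS and a locus is 0 inside the locus
and otherwise the coordinate gap to the nearer end (a TSS one bp upstream
of a locus is at distance 1); the gene-level distance is the minimum over
its transcript TSSs to any active locus, and adjacency is inclusive
(<= 50 kb, "within 50 kb"). `adjacency_sweep()` re-evaluates the split at
20/50/100/200/500 kb for sensitivity analysis. A locus is *active* when
detected in more than 0.5% of cells (strict) in any expression dataset,
or overlapping any epigenetic peak set — an OR rule, so adding datasets
can only grow the active set.

# Insertion dating

Inputs are (i) an old-to-young ordering of the subfamily's loci — in
practice derived from a phylogenetic tree of the loci; any supplied order
is accepted, and results are conditional on it — and (ii) a
presence/absence/missing table of orthologous insertions across
chimpanzee, gorilla, orangutan, gibbon, macaque and marmoset.

Tree preparation utilities implement the fixed MSA filter (drop columns
with < 85% site coverage, then drop sequences with > 15% gaps over the
remaining columns — in that order, since column removal changes sequence
gap fractions) and a one-pass outlier screen that removes leaves whose
standardized external branch length exceeds 3. The screen is run once, on
the preliminary tree, not iterated to convergence: repeated z-screening
keeps shrinking the SD and would eventually bite into ordinary branches.

For each species a 10-locus window slides from old to young; a window
qualifies when more than 3 of its 10 loci (i.e. >= 4) have an orthologous
insertion, with missing values counted as not-present — the window exists
precisely because the ortholog table has substantial missing data, and
counting missing as present would defeat it. The boundary for a species
is the youngest *present* locus inside the youngest qualifying window:
the last copy that reliably predates the divergence. The windowing makes
that choice robust to isolated spurious ortholog calls younger in the
order. All loci strictly older than the boundary are flagged
pre-divergence. On complete synthetic staircases this recovers every
planted branch except the boundary locus itself (the estimator is exact
away from branch boundaries); taking the window *end* as the boundary
instead would systematically overshoot each branch by
`window - min_present` loci, which is why that reading was rejected.

Branch labels follow the deepest flagged species: pre-gibbon HCGOG,
pre-orangutan HCGO, pre-gorilla HCG, pre-chimpanzee HC, otherwise H
(human-specific). Conflicting flag patterns (deep species flagged,
shallow not) resolve to the deepest flag with a warning. Macaque and
marmoset flags are computed — they calibrate contamination from older
subfamilies — but never generate labels beyond HCGOG. A gene inherits the
label of its associated loci when unique; conflicting or missing locus
labels yield ND (not determined).

# Polymorphism calling

A reference TE insertion absent from an individual's allele leaves a
signature in whole-genome sequencing: reads that span the empty site map
as split alignments whose two segments flank the annotated element. The
caller keeps primary, soft-clipped records carrying a supplementary-
alignment (`SA`) descriptor — supplementary and secondary records are
excluded, duplicate read ids collapsed — resolves both segments' mapped
spans, and discards cross-chromosome pairs. A read supports a locus when
the left segment's inner breakpoint falls within 25 nt of the locus's
left end *and* the right segment's within 25 nt of the right end: the
two segments must flank opposite sides, the only geometry consistent with
a read "skipping" the element. One read contributes at most one event per
locus. An individual is called as lacking at least one allele when two or
more skipping reads support the locus (the 2-read floor guards against
index hopping and similar artifacts); cohort summaries count samples
lacking each locus. Calls are monotone in the threshold, and on simulated
cohorts the called set equals the planted set whenever the junction-read
depth meets the threshold, with zero false calls from noise reads.

# The synthetic-data module

Every pipeline input can be generated with known ground truth, so each
caller's sensitivity and specificity are measurable without external
downloads.

* **Expression.** Negative-binomial counts (mean x dispersion
  parameterisation) over eight cell types, 200 cells each by default,
  with 2,000 genes in four truth classes (100 shared-up, 100
  PGCLC-only, 100 naive-only, 1,700 null), a 4-fold effect and
  dispersion 0.3 at a mean library size of 10,000 — magnitudes typical of
  moderately deep droplet scRNA-Seq after filtering. Upregulated genes
  receive the full effect in PGCLC and naive cells and `effect^0.5` in
  MLC — half the effect on the log scale, mirroring the 0.5 model
  weight; halving the multiplier itself would plant a *down*regulation
  whenever the effect is below 2 and would break the `effect = 1` null.
  Planted signal genes draw their baseline rates from the upper half of
  the lognormal baseline distribution: shared-up genes in this system
  are robustly expressed transcripts, and a fold change planted on a
  tail-of-distribution gene is not identifiable on the relative scale
  any method observes. The generator does not emulate doublets, ambient
  RNA or batch effects, so passing recovery tests demonstrate the
  statistics, not robustness to those artifacts.
* **Genome.** TE loci per subfamily (with Smith-Waterman-style
  reliability scores above the 2,500 load filter), peak sets with an
  exactly planted TE-overlap count, and strand-aware TSSs, all placed
  uniformly with rejection sampling (cap 1,000 tries) so that non-planted
  peaks avoid TE loci entirely and planted overlap counts are exact.
* **Ortholog history.** Loci are assigned insertion branches
  (30/15/15/15/25% across HCGOG/HCGO/HCG/HC/H by default — oldest-heavy,
  as expected for a subfamily whose expansion began before the gibbon
  split but continued into the human lineage), ordered oldest-first, and
  the implied presence staircase is masked to missing at the designed
  rate.
* **Reads.** For each planted absent locus, junction reads are emitted as
  soft-clipped SAM records whose `SA` segment maps across the element;
  noise reads are soft-clipped records whose breakpoints lie in TE-free
  territory, > 25 nt from every element boundary. Base sequences are
  arbitrary; the caller never reads them.

All generators restore the caller's RNG state and are byte-reproducible
under their design seed.

# Pipeline and reproducibility

`run_all()` executes the stages in dependency order on a single
configuration (an R list or YAML file), writing one TSV per stage plus a
JSON summary with a config hash and the seed. One master seed is expanded
into fixed per-stage streams, so skipping or swapping a stage (e.g.
supplying an external DE table) leaves every other stage's randomness
unchanged; reruns are byte-identical. Default problem sizes — 1,600
cells, 2,000 genes, a 3.5-Mb two-chromosome genome with 100 TE loci, 200
dated loci, a 20-sample cohort — were chosen so a full run completes in
well under a minute on one core while leaving every statistic in a
regime where its behaviour is measurable (permutation expectations well
above zero, window dating with multiple boundaries, cohort-level allele
counts).

# Known limitations

* The stand-in differential test is rank-based; subtle count-model
  effects (shrinkage, dispersion outliers) require the adapter path.
* Dating accuracy is conditional on the supplied locus order; a poorly
  resolved tree degrades it in ways the synthetic staircase does not
  model.
* The split-read caller genotypes presence/absence of *reference*
  insertions only; non-reference insertion discovery is out of scope.
* Interval statistics assume a single reference; no liftover or
  assembly-gap handling is performed.
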