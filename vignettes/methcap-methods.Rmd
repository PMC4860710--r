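---
title: "Methods: differential methylation, feature enrichment, and
  methylation-anchored GSEA in methcap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation, feature enrichment, and methylation-anchored GSEA in methcap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`methcap` implements an integrative methylome/transcriptome analysis for
methyl-capture (MeDIP-style) sequencing of case/control designs with
several disease models: region-level differential methylation calling from
tag counts, genomic-feature enrichment statistics, cross-model overlap
calculus, differential expression, and methylation-anchored preranked gene
set enrichment analysis (GSEA). A seeded synthetic-data generator with
planted, queryable truth provides the substrate on which every statistical
guarantee of the pipeline is tested. This vignette explains the models,
the tunable parameters, and the design decisions; it states no empirical
result that the test suite and `scripts/acceptance.R` do not themselves
compute.

## The measurement model

Methyl-capture sequencing enriches methylated DNA fragments and sequences
them as short single-end tags. Methylation is therefore inferred from
relative tag-count enrichment over genomic regions — not per-base, and not
on an absolute scale. The pipeline's unit of observation is the count of
deduplicated tags per region per sample, assumed negative binomial:

$$y_{rs} \sim \mathrm{NB}(\mu_{rs},\ \phi), \qquad
  \mu_{rs} = \lambda_r \cdot \ell_s f_s \cdot 2^{\beta_r x_s},$$

with region intensity $\lambda_r$, library size $\ell_s$, TMM factor
$f_s$, group indicator $x_s$ (0 control, 1 injury), region effect
$\beta_r$ (log2 fold change), and common dispersion $\phi$. The same model
is applied to gene/transcript read counts for expression.

## Region discovery

Real studies discover candidate regions with a peak caller run on all
pairwise sample combinations. `propose_candidate_regions()` implements a
deliberately simplified, fully specified surrogate: the genome is tiled
with sliding windows (default width 300 bp, step 150 bp — four times and
twice the 75 bp shift scale typical for 200–300 bp fragments); for every
ordered sample pair (A, B), each window is tested for enrichment of A's
count over the expectation scaled from B (`countB * libA / libB`, floored
at a pseudocount of 1 to avoid a degenerate zero rate) with a Poisson
upper-tail test at cutoff 1e-5; significant windows are pooled over all
pairs and merged bookended. This preserves the pipeline topology of
pairwise discovery → merge → count → test while remaining amenable to an
enumeration oracle; it makes no claim to reproduce any particular peak
caller's shifting model or local background. The union over *all* ordered
pairs is the default; restricting to cross-group pairs is available via
`pairs = "cross"`.

## Differential testing

Both the methylation and the expression arm share one core
(`diff_count_test()`):

1. **Abundance filter.** Rows whose count sum falls below a percentile of
   all row sums are removed — the 50th percentile for regions, the 30th
   for genes. The percentile is computed by linear interpolation between
   order statistics and ties at the threshold are retained.
2. **TMM normalization.** One scaling factor per library from doubly
   trimmed (30% on M-values, 5% on A-values), precision-weighted mean
   log-ratios against a reference sample (the one whose upper quartile is
   closest to the mean upper quartile); factors are rescaled to geometric
   mean 1.
3. **Dispersion.** A common $\phi$ by conditional maximum likelihood on
   quantile-adjusted (equalized) libraries; an optional tagwise
   weighted-likelihood shrinkage exists but the default is the common
   value, which is the defensible choice at 3–5 samples per group.
4. **Exact test.** Conditional on each row total after quantile
   adjustment to a common effective library size, the two-sided p-value
   aggregates splits as or less probable than observed (doubled smaller
   tail, capped at 1). Log2 fold changes use group-average CPM with a
   prior count of 0.5 so they stay finite at zero counts; the prior never
   touches the p-value.

These steps are delegated to edgeR's classic (qCML) machinery, which is
the canonical implementation of this exact methodology; the package's test
suite holds them against independent oracles — a straight-from-the-formula
TMM reimplementation, and the closed-form conditional binomial law for the
1-vs-1, equal-library, $\phi = 0$ case. Raw p-values are thresholded
directly (0.01 for region heatmaps/enrichment, 0.001 for DE lists, GSEA
gene sets and integration); no multiplicity adjustment is applied to the
differential tests, which is a deliberate property of the downstream
overlap logic (evidence must recur across models or data types) rather
than of any single list.

## Feature enrichment

Eleven feature classes are materialized from a gene table: CpG islands,
SNPs, promoters (200 bp and 5 kb upstream of the TSS, strand-aware,
clipped at chromosome ends), TSSs, gene bodies (UTRs included), 5'UTRs,
coding exons (exons minus UTRs), introns (gene body minus exons), 3'UTRs,
and non-genic regions. *Non-genic* is defined here as the genome
complement of gene bodies **and** 5 kb promoters (configurable to exclude
gene bodies only). The unit of analysis is the tested region: for each
feature and direction, a 2x2 table compares differential vs
non-differential regions overlapping (>= 1 bp) vs not overlapping the
feature. Features are not mutually exclusive — one region may count toward
several classes. Odds ratios use the Haldane–Anscombe +0.5 correction only
when a zero cell occurs; the Woolf interval
$\ln \mathrm{OR} \pm 1.96\sqrt{1/a + 1/b + 1/c + 1/d}$ is reported on the
log2 scale; Fisher's exact test is always computed on uncorrected cells.
A hyper-vs-hypo contrast per feature is emitted alongside.

## Cross-model calculus

Regions from two models are *common* when they overlap by at least one
base and their methylation changed in the same direction; opposite-
direction overlaps are reported separately. Venn-style counts use the
anchor convention: a region counts once however many partners it
overlaps, and a triple-common region must have same-direction partners in
both other models. Heatmap preparation z-scores each row within each
model's block of samples (constant rows map to zero with a warning);
clustering uses complete linkage on `1 - Pearson` distance with
`stats::hclust`'s deterministic tie handling, and a constant profile is
assigned distance 1 to everything by convention. Dendrograms export as
Newick.

## Preranked GSEA

Expression results are collapsed to one score per gene:
$s_g = -\log_{10}(p) \cdot \mathrm{sign}(\mathrm{logFC})$ of the gene's
lowest-p transcript, with p floored at 1e-300. Gene sets are derived from
the methylation arm at p < 0.001: a gene joins set *(feature, increased)*
when a hypermethylated region overlaps that feature of the gene, for
feature in {5 kb promoter, CpG island within the promoter, TSS, 3'UTR,
coding exon, intron, 5'UTR}, and likewise *decreased* for hypomethylated
regions. The enrichment score is the weighted Kolmogorov–Smirnov running
sum with weight exponent 1 (the standard "weighted" statistic; assumed,
since only the preranked method is prescribed). The null is gene-set
(label) permutation — `n_perm` random same-size sets, default 1000 —
never phenotype permutation. NES divides the ES by the mean magnitude of
same-sign null ES; the FDR q follows the classic pooled-null procedure
(tail fraction of pooled sign-normalized null NES over the tail fraction
of observed NES, conditioned on sign, capped at 1), with an empirical
per-set p alongside. Significance is declared at FDR < 0.25. Ties in the
ranking are broken by gene id and the permutation stream is seeded, so
results are bit-reproducible.

## The synthetic-data generator

`sim_config()` freezes the study conditions; `generate_annotation()`,
`simulate_methylation()` and `simulate_expression()` produce every input
with planted truth. Defaults, and why:

| parameter | default | rationale |
|---|---|---|
| genome | 2 x 5 Mb | large enough for ~6000 disjoint regions and 400 genes, small enough for per-base oracles elsewhere |
| genes | 400, 5–15 kb, 3–10 exons | gives promoters/UTRs/introns realistic relative footprints |
| samples | 5 per group, 2 groups, 3 models | matches the 4–5 per group typical of such designs |
| dispersion phi | 0.15 | biological replicate variability typical for tissue RNA/capture counts |
| region intensity | log-normal, mean 50 tags, log-sd 0.5 | capture enrichment spans roughly an order of magnitude across regions |
| library factors | log-normal, CV 0.2 | realistic sequencing-depth spread |
| differential fraction | 5% per model, logFC ±2 | strong but not caricatural effects |
| placement odds | gene-body 2.0 for hyper, non-genic 2.0 for hypo | the qualitative signature the pipeline must recover |
| hypo eligibility | top 10% baseline intensity | see below |
| coupling | promoter, strength −1.5 | increased promoter methylation represses the transcript; sign recoverable by GSEA |
| sharing | 0 | models plant on disjoint regions, so cross-model overlap is chance-level by construction |

Two structural choices deserve emphasis. First, **hypomethylation is
planted only on regions in the upper baseline-intensity range** (top 10%
by default): a capture assay can only lose signal where methylation was
dense to begin with. This is not merely cosmetic — the 50th-percentile
abundance filter removes low-sum rows, and a 4-fold loss pushes an
average-intensity region far below that cut; without the eligibility rule
most planted hypomethylation would be silently filtered and the generator
would fail to emulate the abundant, detectable hypomethylation that
motivates the analysis. Second, **models plant disjointly unless sharing
is requested**: with a shared baseline field and a finite eligibility
pool, independent planting would concentrate hypomethylation on the same
regions in every model and fabricate cross-model overlap; exclusivity
makes `sharing = 0` mean what it says. A corollary is that later models
draw from a depleted eligible pool, so their feature bias is somewhat
attenuated relative to the first model — feature profiles are partly
model-specific, as they are in real multi-model comparisons.

Feature-biased placement draws the number of in-feature picks binomially
at the target odds applied to the pool's composition, then samples
uniformly within the in/out strata and shuffles; this realizes the target
odds without the depletion bias a sequential accept/reject scheme incurs
when sampling without replacement. Methylation-expression coupling sums
over all planted events hitting a gene's coupled features, so opposing
events cancel rather than racing for the last word.

The generator emits either region count matrices (the fast path used by
most tests) or raw tag tracks (positions of fixed-length 36 bp tags,
background rate 2e-4 tags/bp), which exercise deduplication, window-based
proposal and region counting. Everything is deterministic given the
config seed; each stage derives its own stream from it.

### What the generator does not emulate

No sequence content, mappability, GC or CpG-density-dependent capture
efficiency, fragment-length variation, strand asymmetries, or correlated
(co-methylated) neighboring regions; gene bodies never overlap, and
expression is independent across genes apart from the planted coupling.
Passing the planted-truth tests therefore demonstrates that the
*statistical machinery* recovers the structure it is designed for — not
that it is robust to every artifact of real capture data.

## Numerical choices and degenerate inputs

- Coordinates are 0-based half-open (BED convention) in every public
  interface; the 1-based internal representation is confined to the
  container layer. Bookended intervals merge at `min_gap = 0`; overlap
  always means at least one shared base.
- Sorting and tie-breaks are fixed everywhere (chromosome lexicographic,
  then start, then end; gene id for rank ties; lowest index in linkage),
  so every table is byte-reproducible under a fixed seed.
- Empty inputs degrade explicitly: an empty candidate set yields an empty
  DMR list with a warning; an empty DMR set yields an empty gene-set
  collection with a warning (the downstream report shows "analysis not
  available"); a zero-count matrix yields dispersion 0 with a warning;
  a direction with no regions is flagged non-estimable rather than
  silently dropped.
- Library sizes default to total tag counts before row filtering
  (configurable), not post-filter column sums.
- The p-value floor for rank scores is 1e-300; BED scores cap at 1000.

## Problem sizes used by the tests

The suite validates interval arithmetic against per-base brute-force
oracles on random instances of a few kilobases; Fisher's test against
full hypergeometric enumeration for small-to-moderate margins; TMM
against the formula oracle on dozens of random matrices; type-I error on
null data of 5000 regions and 2000 genes; and the planted-truth
recoveries (feature odds, GSEA coupling, sharing, clustering) on 20
seeded replicates of the default conditions. These sizes were chosen so
the whole suite runs in a few minutes on a single core while keeping
Monte-Carlo error well inside each check's margin.

## Known limitations

- The window-based region proposal is a surrogate, not a reimplementation
  of any published peak caller; absolute candidate counts differ from
  MACS-style callers even on identical tags.
- The classic common-dispersion exact test is used as published; the
  moderation constants of more recent shrinkage estimators are
  deliberately not chased, since they are not recoverable from the
  methodology this package mirrors.
- Woolf intervals undercover slightly when the DMR lists are contaminated
  by false positives (the planted odds are diluted); the acceptance
  checks account for this by bounding coverage from below rather than
  asserting nominal coverage.
- Overlapping genes are not supported by the annotation builder's
  intron/exon set algebra (the generator never produces them; real
  annotations would need pre-flattening).
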