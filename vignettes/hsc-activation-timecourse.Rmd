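---
title: "Cross-model time-course analysis of hepatic stellate cell activation"
author: "stellate package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-model time-course analysis of hepatic stellate cell activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stellate)
```

## The problem

Hepatic stellate cells (HSCs) transdifferentiate from a quiescent,
vitamin-A-storing state into extracellular-matrix-producing myofibroblasts
during liver injury — the central cellular event of liver fibrosis. Three
experimental systems are commonly used to drive this activation: chronic
Western-diet feeding (WD, sampled here at 0/12/16/24 weeks), repeated
carbon-tetrachloride injury (CCl4, 0/1/4/8 weeks), and spontaneous
activation of isolated HSCs in culture (IVT, 0/1/4/8/12 days). A gene
program that behaves the same way in all three systems, despite their very
different kinetics and pathology, is a strong candidate for a core
activation program, and the promoter motif content of such a program
points at its upstream regulators.

`stellate` implements that comparative analysis as a pipeline:

1. per-model differential expression by a conditional negative-binomial
   (NB) exact test;
2. selection of *common* genes — regulated at least 4-fold (FDR < 0.05)
   between some pair of time points in every model, in a concordant
   direction;
3. time-course clustering of the common genes by k-medoids under Pearson
   correlation distance, with silhouette-based selection of k and a fit
   filter;
4. pairing of clusters across models by prototype correlation and
   extraction of *shared* genes;
5. proximal-promoter (−300; +50) PWM scanning for ETS1/ETS-family, RUNX1
   and AP-1 motifs with ZOOPS hypergeometric enrichment;
6. motif-conditional induction statistics: fold-change comparisons between
   motif groups (pairwise exact Wilcoxon, BH-corrected, compact letter
   display), induction-rank analysis, cluster × motif enrichment, and
   generic gene-set over-representation.

Because the full animal study cannot be regenerated at a desk, the package
ships a synthetic-data generator that emulates the three designs with
*planted* truth — cluster memberships, motif placements, effect sizes — so
every stage can be verified against ground truth, and the pipeline's
statistical machinery is validated by independent oracles (enumeration,
brute force, closed forms) in the test suite.

## Differential expression

Counts for gene *g* in a group of *n* replicates are modelled NB with mean
*μ* and common dispersion *φ* (variance *μ + φμ²*). The two-group test
conditions on the gene's total count across both groups after library
sizes are equalized by pseudo-count scaling (each sample rescaled to the
geometric-mean library size and rounded — the standard precondition of the
conditional test). Under the null, the split of the total *t* between
groups of *n~A~* and *n~B~* replicates follows a negative hypergeometric
distribution with shapes *n~A~/φ* and *n~B~/φ*; at *φ = 0* it reduces to a
binomial split. The two-sided p-value sums the probabilities of all splits
no more likely than the observed one ("small probabilities" flavour). The
test suite checks this against direct enumeration of the joint NB
probabilities and against an independent implementation of the same
statistic in `edgeR`.

Choices that matter:

* **Dispersion** — a single common *φ* per experiment, estimated by the
  pooled method of moments `sum(var − mean) / sum(mean²)`, floored at 0.
  No tagwise or trended shrinkage: the common-φ model is the minimal
  faithful model and is what the conditional test conditions on.
* **Normalization** — total-count library sizes (CPM/RPKM), no TMM. The
  synthetic data carry their true library sizes in the sample sheet, so
  composition bias does not arise; for user data with strong asymmetric
  regulation a compositional normalization would be needed upstream.
* **Prior count** — 0.5 on the CPM scale for all log2 values and fold
  changes, so zero counts map to finite values (`log2(0 + 0.5) = −1`).
* **Expression floor** — genes are tested only when their mean log2CPM
  across *all* samples of the experiment exceeds 2 (one per-experiment
  threshold); excluded genes get an `NA` FDR and do not count towards the
  number of BH tests.
* **Global activity shift** — the package also tests whether the whole
  per-gene expression distribution moves up on activation, by a paired
  two-sided Wilcoxon signed-rank test on per-gene mean log2CPM (exact,
  tie-aware, up to 30 non-zero differences; normal approximation with
  continuity correction beyond).

## Common genes

A gene is flagged *induced* in a model when any later-vs-earlier contrast
shows log2FC ≥ log2(4) with FDR < 0.05 — a closed bound on the fold change
and a strict bound on the FDR — and *repressed* symmetrically. "Between
any two time points" is read literally as all ordered later-vs-earlier
pairs, including against the control point. The common set is the
intersection across models within one direction; genes flagged in both
directions within a model, or with conflicting directions across models,
are excluded and reported. This makes the selection monotone: raising the
fold threshold or lowering the FDR threshold can only shrink the set.

## Clustering

Per-time-point average RPKM profiles of the common genes are
variance-stabilized with log2(x + 1) and z-scored per gene. Scaling uses
the sample standard deviation (divide by n − 1, the `stats::sd()`
convention): the worked reference value for the row (0, 1, 3, 7) is
(−1.1619, −0.3873, 0.3873, 1.1619). Rows constant after the transform
cannot be scaled and are excluded with a flag.

Clustering is k-medoids under d = 1 − r (Pearson). Two solvers stand
behind one interface: instances with at most 3000 candidate medoid sets
are solved *exactly* by exhaustive enumeration — the swap heuristic stalls
in local optima on a noticeable fraction of small instances — and larger
instances use PAM's deterministic BUILD + swap phases via
`cluster::pam()`. Both routes are deterministic; no seed enters the
clustering. k is chosen to maximize the average silhouette width over a
candidate range (default 2–12), ties resolving to the smallest k.

The fit of a gene is the Pearson correlation to its own cluster's
prototype (the arithmetic mean of member profiles). The fit filter is
*global*: the lowest 10% of fits across all clusters are discarded (floor
of n × 0.10 genes, ties broken by gene id) — we read "least fitting" as
one pooled quantile, configurable. Afterwards the single smallest cluster
is removed post hoc if it falls below `min_cluster_size` (default 20), a
configurable mirror of removing only an undersized outlier cluster rather
than a fixed-size rule. Prototypes and fits are recomputed on the
retained genes; removing the worst fits can only raise the mean
member-to-prototype correlation, which the tests assert as a property.

A known behaviour worth stating: with only 4 ordinal time points,
biologically realistic profile shapes are strongly correlated, and the
average silhouette then favours the coarse induced-vs-repressed
bipartition (k = 2) over the finer planted structure. The k-selection
criterion recovers the true k reliably when prototypes are well separated
(pairwise |r| < 0.3, as in the validation simulations); on highly
correlated shapes it deliberately under-splits rather than over-split.

## Cluster pairing across models

Cluster prototypes of two models are compared on their ordinal time axes;
if the axes differ in length the shorter prototype is linearly
interpolated onto the longer ordinal grid (with equal lengths, as for the
two in vivo designs, no interpolation happens). The one-to-one pairing
maximizes the total Pearson correlation by an exact assignment solver
(bitmask dynamic programming) — deterministic and order-independent,
unlike greedy matching. Pairs whose best achievable correlation is
negative are returned but flagged low-confidence. Shared genes are plain
intersections of member sets, reported with the percentage of the
first-model parent cluster. Overlap significance is the upper-tail
hypergeometric probability P(X ≥ overlap); the universe is the set of
genes retained by the fit filter in *both* models — genes discarded in
either model were never eligible for the overlap — and the cluster margins
are restricted to that universe for consistency.

## Promoter motif analysis

Promoters are the fixed window (−300; +50) around the annotated TSS in
transcription orientation: on the plus strand the half-open genomic
interval [tss − 300, tss + 50), on the minus strand
[tss − 49, tss + 301) reverse-complemented; TSS coordinates are 0-based.
Genes whose window leaves the contig are excluded and logged; sequences
over 50% N are flagged.

PWMs are read from JASPAR-style count matrices; each column receives a
total pseudocount of 0.8 distributed by the background composition
(uniform 0.25 by default) before conversion to base-2 log-odds. A site is
called where the window's log-odds score reaches 80% of the PWM's maximum
achievable score, on either strand — a transparent fractional threshold in
place of an external scanner's unstated rule. Scanning both strands of
equal-width promoters is vectorized over genes; the tests confirm exact
agreement with naive per-window rescoring and the strand-symmetry
invariant (scanning reverse complements mirrors the hit set with strands
flipped).

Gene-level statistics use ZOOPS (zero-or-one occurrence per sequence)
binarization: a motif is "present" when at least one site is called.
Families can be collapsed by OR (any of the ETS-family PWMs counts as
`ETS1_like`). Enrichment of a motif in a target set against a background
(default: all genes with extractable promoters) is upper-tail
hypergeometric on presence, BH-corrected across motifs, with the fold
ratio of presence frequencies. Motif spacing between two factors is the
minimal midpoint-to-midpoint distance per co-occupied promoter, averaged
across such promoters — the spacing measure is a documented choice, since
midpoints make the value width-invariant.

## Motif-conditional induction statistics

The common genes are partitioned four ways by presence of two motifs
(default: ETS1 family and RUNX1): none / A-only / B-only / both. Group
fold changes for a chosen contrast (default: final time vs control of the
first clustered model, matching the headline "final week vs control"
comparisons) are compared by pairwise two-sided Wilcoxon rank-sum tests —
exact and tie-aware up to 50 observations per group via dynamic
programming over doubled ranks, normal approximation with continuity and
tie correction beyond — BH-corrected across pairs. The compact letter
display assigns letters by connected components of the
non-significant-pair graph: groups not sharing a letter differ at
FDR < 0.05. We letter by the rank-sum test's significance (a test on
distributions), not on means. Rank analysis sorts genes by log2FC
descending (rank 1 = most induced, average ranks on ties) and reports
median ranks per group.

Cluster × motif tables count, for every cluster (plus "no cluster" for
fit-filtered genes), the genes carrying each motif, the enrichment ratio
(count/cluster size)/(motif total/universe), and the upper-tail
hypergeometric probability; counts across clusters add up to the motif
total, which the tests assert.

Over-representation analysis takes a foreground against a background of
*expressed* genes — both restricted to RPKM ≥ 10 (closed bound) in at
least one time-point average of any model — tests each gene set by
upper-tail hypergeometric, BH-corrects across sets, and flags sets at
FDR ≤ 0.01, reporting the median log2FC of each set's foreground members.

## The synthetic study

`synthetic_config()` defines the emulated study; its defaults *are* the
study conditions and are not tuned per analysis:

* **Design** — three models with the time courses above, 3 replicates per
  point (the emulated study used 3–4), 5000 genes.
* **Counts** — NB with common dispersion φ = 0.1 (a typical bulk RNA-seq
  value for inbred replicates); baseline means 2^Normal(5, 2) in CPM-like
  units, giving a realistic dynamic range that exercises the log2CPM > 2
  and RPKM ≥ 10 filters; library sizes uniform in [0.8, 1.2] × 10⁶ so
  CPM ≈ count and worked examples stay legible. Exonic lengths are
  log-normal around 1.5 kb.
* **Programs** — 30% of genes carry one of six planted temporal profiles
  (70% are null). The shapes are specified on the scaled axis and
  converted to log2FC trajectories by per-program amplitudes; they include
  a strongly repressed monotone program (`cluster1`, amplitude 3) and a
  strongly induced linear program (`cluster6`, amplitude 4), plus
  transient and delayed shapes. Profiles are evaluated on each model's
  ordinal time grid, emulating conserved topography across models with
  different clocks.
* **Motif coupling** — genes of the induced program receive a dual
  ETS1 + RUNX1 promoter placement with probability 0.6 (lone placements
  at 0.15 each otherwise); background genes carry ETS1/RUNX1/AP-1 at
  0.12/0.05/0.10; AP-1 rises to 0.30 in the induced program. Regulated
  genes carrying both ETS1 and RUNX1 receive an extra +2 log2FC at the
  final time point, ramped along the ordinal axis — the planted
  motif/induction coupling that the induction statistics must detect.
* **Promoters and genome** — 350 bp promoters with planted sites sampled
  from the PWM conditioned on exceeding the 80% calling threshold (planted
  sites are functional sites by construction; rejection sampling, with the
  consensus as fallback). Sites are placed uniformly without overlap, on a
  random strand. Genes are tiled on synthetic contigs (100 genes per
  contig, 2 kb flanks) so no promoter window can overflow; the written
  FASTA/annotation round-trips every planted instance exactly.
* **PWMs** — six synthetic motifs: ETS1 plus three ETS-family variants
  sharing the GGAA core (collapsed to `ETS1_like`), RUNX1 and AP-1. Each
  has one two-base degenerate column and otherwise sharp columns, so the
  80% threshold admits the degenerate variants and no other mismatch;
  expected false hits are ≲0.01 per promoter per motif.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: gene–gene correlation (genes are independent
draws), batch or replicate-level structure beyond NB noise, composition
bias (true library sizes are carried), isoforms and length biases, GC
effects, real PWM information content (genomic PWMs are softer, so real
scanning has a harder sensitivity/specificity trade-off), and positional
preference of sites within promoters (placements are uniform, so the
planted spacing statistic reflects window geometry, not biology).

All randomness derives from one master seed through fixed per-stage
substreams, so `generate_truth()`, `simulate_counts()` and the file
writers are individually reproducible and two runs of the pipeline with
one seed produce byte-identical output files.

## Numerical choices and degenerate inputs

* Exact-vs-approximate switch points: rank-sum exact up to 50 per group,
  signed-rank exact up to 30 non-zero differences; both exact paths
  handle ties by dynamic programming over doubled average ranks. All
  zero differences define p = 1.
* The NB exact test computes the conditional log-pmf in closed form via
  `lchoose` and sums probabilities ≤ observed with a 1 + 1e−12 relative
  guard; all-zero genes give p = 1.
* Exhaustive k-medoids is used when choose(n, k) ≤ 3000; tie-breaks are
  by enumeration order, and the fit filter breaks ties by gene id.
  Silhouette ties resolve to the smallest k; degenerate (all-identical)
  inputs return the smallest candidate k with a warning.
* Constant profile rows, genes with undefined fits (degenerate
  prototypes) and promoters that leave their contig are excluded and
  reported rather than silently dropped; undefined fits sort as worst in
  the fit filter.
* The hypergeometric helpers validate margins (overlap ≤ min of the set
  sizes ≤ universe) and return exact tail sums via `phyper`.

## Validation scale

The test suite validates the machinery at deliberately small problem
sizes chosen so the full suite stays fast while estimates remain stable:
exact-test oracle comparisons at totals ≤ 200; null calibration at 2000
genes with 4 vs 4 replicates; clustering oracle equivalence at n ≤ 12;
planted-recovery simulations at 600 genes over 100 seeds; scanner checks
on 500–1000 promoters; and 50 seeded end-to-end runs at 400 genes for the
dual-motif coupling property. The acceptance script runs the pipeline at
the full default scale (5000 genes).

## Known limitations

* Numeric parity with the external tools used in the emulated study
  (edgeR-through-Homer, TiCoNE, Homer motif discovery, Metacore) is not
  claimed; the contract is parity with the brute-force definitions of the
  statistics, which the tests enforce.
* The common-dispersion model understates variance for genes with
  atypical dispersion; tagwise shrinkage is out of scope.
* De novo motif discovery is out of scope: scanning requires a PWM
  collection. Known-PWM scanning plus hypergeometric enrichment
  reproduces the scoring stage, not motif discovery itself.
* With few time points, silhouette-based k selection merges correlated
  programs (see Clustering above); the planted generator keeps its
  realistic, correlated default shapes rather than artificially
  orthogonal ones.
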