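# stellate

Time-resolved, cross-model analysis of hepatic stellate cell (HSC)
activation transcriptomes.

HSCs drive liver fibrosis: on injury they transdifferentiate from
quiescent, vitamin-A-storing cells into matrix-producing myofibroblasts.
`stellate` asks which gene programs behave identically across three very
different activation systems — Western-diet feeding (weeks 0/12/16/24),
carbon-tetrachloride injury (weeks 0/1/4/8) and in vitro
transdifferentiation (days 0/1/4/8/12) — and whether the promoter motif
content of the conserved induced program (ETS1-family, RUNX1, AP-1 binding
sites) predicts how strongly a gene is induced. It is written for
computational biologists analysing multi-model time-course RNA-seq with
promoter-level regulatory follow-up.

## What it computes

* **Differential expression** — conditional negative-binomial exact test
  with a common dispersion φ per experiment. Counts are NB(μ, φ) with
  variance μ + φμ²; after pseudo-count equalization of library sizes the
  split of a gene's total t between groups of n_A and n_B replicates is
  negative hypergeometric with shapes n_A/φ and n_B/φ (binomial when
  φ = 0), and the two-sided p sums the probabilities of all splits no more
  likely than the observed one. BH-FDR over genes passing a mean
  log2CPM > 2 floor.
* **Common genes** — genes changed ≥ 4-fold (FDR < 0.05) between some pair
  of time points in *every* model, same direction everywhere.
* **Time-course clustering** — per-gene scaled log2(RPKM+1) profiles,
  k-medoids under d = 1 − r (Pearson), k by average silhouette, global
  10% fit filter, post-hoc removal of an undersized smallest cluster.
* **Cluster pairing** — optimal one-to-one assignment of cluster
  prototypes across models by total Pearson correlation; shared genes per
  pair; upper-tail hypergeometric overlap probabilities.
* **Promoter motifs** — strand-aware (−300; +50) promoter extraction,
  both-strand PWM scanning at 80% of the maximum log-odds score, ZOOPS
  presence tables, hypergeometric motif enrichment, ETS1–RUNX1 site
  spacing, hit-derived position-frequency matrices.
* **Motif-conditional induction** — common genes partitioned by
  ETS1-family/RUNX1 presence (none / either / both); pairwise exact
  Wilcoxon rank-sum comparisons of log2FC with BH correction and a compact
  letter display; induction-rank analysis; cluster × motif enrichment;
  gene-set over-representation (RPKM ≥ 10 filter, FDR ≤ 0.01).
* **Synthetic study generator** — NB counts for all three designs with
  planted profile clusters, planted promoter motif instances whose
  presence is coupled to induction (+2 log2FC for dual ETS1+RUNX1 genes),
  and on-disk genome/annotation/PWM files that round-trip exactly.

See `vignettes/hsc-activation-timecourse.Rmd` for the methods account.

## Worked example

The numbered drivers under `analysis/` run the whole study on synthetic
data and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R              # genome, annotation, PWMs, counts
Rscript analysis/02_differential_expression.R
Rscript analysis/03_common_genes.R
Rscript analysis/04_clustering.R
Rscript analysis/05_cluster_matching.R
Rscript analysis/06_motif_scanning.R
Rscript analysis/07_induction_statistics.R
```

With the default seed, stage 3 reports

```
common genes across all three models: 955 (743 induced, 212 repressed)
```

and stage 7 prints the headline motif-conditional result:

```
induction by motif group (WD final vs control):
           group   n    median letter
1           none 578 0.3623712      a
2 ETS1_like_only  99 1.0558182      b
3     RUNX1_only  52 1.2365271      b
4           both 226 1.9936946      c

median log2FC both = 1.99 vs none = 0.36; pairwise BH-FDR (both vs none) = 1.09e-54
```

Reading: among the 955 cross-model regulated genes, those whose promoters
carry both an ETS1-family and a RUNX1 site (the planted coupling) are
induced about 3-fold more strongly at the final Western-diet time point
than genes with neither motif, single-motif genes sit in between, and the
letter display shows the dual-motif group is significantly different from
every other group. The same run reports the dual-motif genes' median
induction rank (212.5 of 955) far above the no-motif group (612.5), and
the cluster × motif table concentrates the motif-bearing genes in the
induced cluster.

Equivalently in R:

```r
library(stellate)
run <- run_pipeline(pipeline_config(synthetic = synthetic_config(seed = 1)))
run$report$group_medians
#>           none ETS1_like_only     RUNX1_only           both
#>      0.3623712      1.0558182      1.2365271      1.9936946
```

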