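#!/usr/bin/env Rscript
# Stage 7 — motif-conditional induction statistics.
#
# Groups the common genes by ETS1-family / RUNX1 promoter motif presence,
# compares their induction (WD final time vs control) by pairwise exact
# Wilcoxon rank-sum tests with BH correction and a compact letter
# display, ranks genes by induction, tests the distribution of
# motif-bearing genes over the WD clusters, and runs gene-set
# over-representation per cluster (RPKM >= 10 filter, FDR <= 0.01).

library(stellate)

outdir <- "results"
indir <- "results/synthetic"
common <- read.delim(file.path(outdir, "common_genes.tsv"))
pres_tab <- read.delim(file.path(outdir, "motif_presence.tsv"))
presence <- as.matrix(pres_tab[, -1]); rownames(presence) <- pres_tab$gene
mt <- structure(list(presence = presence), class = "hsc_motif_table")

groups <- assign_motif_groups(common$gene, mt, c("ETS1_like", "RUNX1"))
cat("motif groups over the common genes:\n")
print(table(groups))

de_files <- list.files("results/de", "^de_WD_", full.names = TRUE)
fin <- read.delim(de_files[length(de_files)])
lfc <- setNames(fin$log2FC, fin$gene)[common$gene]

res <- compare_groups(lfc, groups)
cat("\ninduction by motif group (WD final vs control):\n")
print(res$groups)
ra <- rank_analysis(lfc, groups)
print(ra)
cat(sprintf("\nmedian log2FC both = %.2f vs none = %.2f; pairwise BH-FDR (both vs none) = %.3g\n",
            res$groups$median[res$groups$group == "both"],
            res$groups$median[res$groups$group == "none"],
            res$pairs$fdr[(res$pairs$group1 == "both" &
                             res$pairs$group2 == "none") |
                            (res$pairs$group1 == "none" &
                               res$pairs$group2 == "both")]))

cl <- read.delim(file.path(outdir, "clusters_WD.tsv"))
assignment <- setNames(rep("no cluster", nrow(common)), common$gene)
assignment[cl$gene[cl$gene %in% common$gene]] <-
  as.character(cl$cluster[cl$gene %in% common$gene])
motif_sets <- lapply(colnames(presence),
                     function(m) rownames(presence)[presence[, m] > 0])
names(motif_sets) <- colnames(presence)
cme <- cluster_motif_enrichment(assignment,
                                motif_sets[c("ETS1_like", "RUNX1")])
cat("\ncluster x motif distribution (common genes):\n")
print(cme[order(cme$p), ][1:6, ])

# per-cluster over-representation against the planted + decoy gene sets
sets <- read_gmt(file.path(indir, "sets.gmt"))
ann <- read_annotation(file.path(indir, "annotation.tsv"))
rpkm <- do.call(cbind, lapply(c("WD", "CCl4", "IVT"), function(mdl) {
  cm <- read_counts_tsv(file.path(indir, sprintf("counts_%s.tsv", mdl)),
                        file.path(indir, sprintf("samples_%s.tsv", mdl)),
                        annotation = ann)
  timepoint_means(normalize_counts(cm), mdl, "rpkm")
}))
n_enriched <- 0
for (k in sort(unique(cl$cluster))) {
  fg <- intersect(cl$gene[cl$cluster == k], common$gene)
  res_k <- ora(fg, common$gene, sets, rpkm = rpkm[common$gene, ],
               rpkm_floor = 10, fdr_max = 0.01, log2fc = lfc)
  hit <- res_k[res_k$enriched, ]
  n_enriched <- n_enriched + nrow(hit)
  if (nrow(hit)) {
    cat(sprintf("\nWD cluster %s: %d enriched set(s)\n", k, nrow(hit)))
    print(hit[, c("set", "overlap", "fdr", "median_log2fc")])
  }
}
cat(sprintf("\nenriched gene sets across WD clusters (FDR <= 0.01): %d\n",
            n_enriched))

write.table(res$groups, file.path(outdir, "motif_group_comparison.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(res$pairs, file.path(outdir, "motif_group_pairs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ra, file.path(outdir, "motif_group_ranks.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cme, file.path(outdir, "cluster_motif_enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
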