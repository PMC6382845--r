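#!/usr/bin/env Rscript
# Stage 4 — time-course clustering of common genes.
#
# For the two in vivo models: averages RPKM per time point over the
# common genes, variance-stabilizes (log2(x+1)) and scales, selects k by
# average silhouette under Pearson correlation distance, clusters by
# k-medoids, and removes the 10% least fitting genes plus an undersized
# smallest cluster. Writes assignments and prototypes.

library(stellate)

indir <- "results/synthetic"
outdir <- "results"
ann <- read_annotation(file.path(indir, "annotation.tsv"))
common <- read.delim(file.path(outdir, "common_genes.tsv"))

for (mdl in c("WD", "CCl4")) {
  cm <- read_counts_tsv(file.path(indir, sprintf("counts_%s.tsv", mdl)),
                        file.path(indir, sprintf("samples_%s.tsv", mdl)),
                        annotation = ann)
  norm <- normalize_counts(cm)
  avg <- timepoint_means(norm, mdl, "rpkm")[common$gene, , drop = FALSE]
  prof <- vst_scale(avg)
  k <- choose_k(prof, 2:12)
  cs <- fit_filter(pam_cluster(prof, k), drop_frac = 0.10,
                   min_cluster_size = 20)
  pr <- cluster_prototypes(cs)
  cat(sprintf("%s: k = %d; cluster sizes: %s; avg member-to-prototype Pearson r = %.3f; %d genes discarded\n",
              mdl, cs$k,
              paste(table(cs$assignment), collapse = "/"),
              pr$avg_fit, length(cs$discarded)))
  write.table(data.frame(gene = names(cs$assignment),
                         cluster = cs$assignment,
                         fit = cs$fit[names(cs$assignment)],
                         row.names = NULL),
              file.path(outdir, sprintf("clusters_%s.tsv", mdl)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(cluster = rownames(cs$prototypes),
                         cs$prototypes, check.names = FALSE),
              file.path(outdir, sprintf("prototypes_%s.tsv", mdl)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
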