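#!/usr/bin/env Rscript
# Stage 5 — cross-model cluster pairing.
#
# Pairs WD and CCl4 clusters by prototype Pearson correlation (optimal
# one-to-one assignment), extracts the shared genes of each pair, and
# tests each overlap by upper-tail hypergeometric probability against the
# universe of genes retained in both clusterings.

library(stellate)

outdir <- "results"
read_clusters <- function(mdl) {
  cl <- read.delim(file.path(outdir, sprintf("clusters_%s.tsv", mdl)))
  pr <- read.delim(file.path(outdir, sprintf("prototypes_%s.tsv", mdl)),
                   check.names = FALSE)
  protos <- as.matrix(pr[, -1, drop = FALSE])
  rownames(protos) <- as.character(pr$cluster)
  list(assignment = setNames(cl$cluster, cl$gene), protos = protos)
}
wd <- read_clusters("WD"); ccl4 <- read_clusters("CCl4")

pairing <- pair_clusters(wd$protos, ccl4$protos)
shared <- shared_genes(pairing, wd$assignment, ccl4$assignment)
uni <- intersect(names(wd$assignment), names(ccl4$assignment))
aa <- wd$assignment[uni]; bb <- ccl4$assignment[uni]
shared$p <- vapply(seq_len(nrow(shared)), function(i)
  overlap_significance(sum(as.character(aa) == shared$a[i]),
                       sum(as.character(bb) == shared$b[i]),
                       shared$shared_n[i], length(uni)), numeric(1))

cat(sprintf("paired %d cluster pairs; %d shared genes in total (universe %d)\n",
            nrow(shared), sum(shared$shared_n), length(uni)))
for (i in seq_len(nrow(shared))) {
  cat(sprintf("  WD %s <-> CCl4 %s: r = %.3f, shared %d (%.0f%% of WD cluster), hypergeometric P = %.3g\n",
              shared$a[i], shared$b[i], shared$r[i], shared$shared_n[i],
              shared$percent_of_a[i], shared$p[i]))
}
write.table(shared[, setdiff(names(shared), "genes")],
            file.path(outdir, "cluster_pairs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
for (i in seq_len(nrow(shared))) {
  writeLines(shared$genes[[i]],
             file.path(outdir, sprintf("shared_genes_WD%s_CCl4%s.txt",
                                       shared$a[i], shared$b[i])))
}
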