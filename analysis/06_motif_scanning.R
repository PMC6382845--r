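#!/usr/bin/env Rscript
# Stage 6 — proximal-promoter motif scanning.
#
# Extracts (-300; +50) promoters from the written genome and annotation,
# scans all PWMs on both strands at 80% of the maximum log-odds score,
# builds the ZOOPS gene x motif table (ETS family collapsed to
# "ETS1_like"), tests motif enrichment in the common genes against all
# annotated genes, and emits hit-derived position-frequency matrices.

library(stellate)

indir <- "results/synthetic"
outdir <- "results"
ann <- read_annotation(file.path(indir, "annotation.tsv"))
prom <- extract_promoters(file.path(indir, "genome.fa"), ann)
pwms <- read_pwm(file.path(indir, "pwms.jaspar"))
cat(sprintf("extracted %d promoters (%d excluded at contig edges)\n",
            length(prom$seqs), length(prom$excluded)))

hits <- scan_pwm(pwms, prom, threshold_frac = 0.80)
tab <- gene_motif_table(hits, genes = names(prom$seqs),
                        pwm_ids = names(pwms),
                        families = default_motif_families())
common <- read.delim(file.path(outdir, "common_genes.tsv"))
enr <- motif_enrichment(intersect(common$gene, rownames(tab$presence)),
                        rownames(tab$presence), tab)
print(enr)

n_common_motif <- colSums(tab$presence[common$gene, , drop = FALSE])
cat("common genes with motif:",
    paste(sprintf("%s=%d", names(n_common_motif), n_common_motif),
          collapse = ", "), "\n")

spacing <- motif_spacing(hits[hits$gene %in% common$gene, , drop = FALSE],
                         pwms$ETS1, pwms$RUNX1)
cat(sprintf("mean ETS1-RUNX1 spacing in co-occupied common promoters: %.1f bp (n = %d)\n",
            spacing$mean_spacing, spacing$n))

write.table(hits, file.path(outdir, "motif_hits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(gene = rownames(tab$presence), tab$presence,
                       check.names = FALSE),
            file.path(outdir, "motif_presence.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(enr, file.path(outdir, "motif_enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
for (id in c("ETS1", "RUNX1", "AP1")) {
  pfm <- hit_pfm(hits, prom, pwms[[id]])
  write.table(data.frame(base = rownames(pfm), pfm, check.names = FALSE),
              file.path(outdir, sprintf("hit_pfm_%s.tsv", id)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
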