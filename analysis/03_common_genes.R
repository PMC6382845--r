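#!/usr/bin/env Rscript
# Stage 3 — cross-model common genes.
#
# Flags genes regulated >= 4-fold (FDR < 0.05) between some pair of time
# points within each model, intersects the three models requiring a
# concordant direction, and writes the common gene set.

library(stellate)

dedir <- "results/de"
outdir <- "results"
flags <- list()
for (mdl in c("WD", "CCl4", "IVT")) {
  files <- list.files(dedir, sprintf("^de_%s_", mdl), full.names = TRUE)
  de <- lapply(files, function(f) read.delim(f))
  names(de) <- sub(sprintf("^de_%s_(.*)\\.tsv$", mdl), "\\1",
                   basename(files))
  flags[[mdl]] <- regulated_in_model(de, fc_threshold = 4,
                                     fdr_threshold = 0.05)
  cat(sprintf("%s: %d induced, %d repressed (any contrast)\n", mdl,
              sum(flags[[mdl]]$induced), sum(flags[[mdl]]$repressed)))
}
common <- intersect_common(flags)
write.table(as.data.frame(common), file.path(outdir, "common_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("common genes across all three models: %d (%d induced, %d repressed)\n",
            nrow(common), attr(common, "n_induced"),
            attr(common, "n_repressed")))
truth <- read.delim("results/synthetic/truth_genes.tsv")
planted <- truth$gene_id[truth$planted_cluster != "null"]
cat(sprintf("of these, %d carry a planted profile (planted total: %d)\n",
            sum(common$gene %in% planted), length(planted)))
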