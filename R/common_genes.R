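# Cross-model "common" gene selection: genes regulated at least fc-fold
# (FDR below threshold) between some pair of time points in every model,
# in the same direction everywhere.

#' Flag genes regulated within one model
#'
#' A gene is flagged induced if any later-vs-earlier contrast shows
#' log2FC >= log2(fc_threshold) with FDR < fdr_threshold (closed
#' fold-change bound, open FDR bound); repressed analogously with
#' log2FC <= -log2(fc_threshold). A gene can carry both flags (from
#' different contrasts); the conflict is resolved in [intersect_common()].
#'
#' @param de_list list of [de_table()] results for the model's
#'   later-vs-earlier contrasts (e.g. from [model_contrasts()]).
#' @param fc_threshold fold-change threshold on the natural scale
#'   (default 4).
#' @param fdr_threshold FDR threshold, strict (default 0.05).
#' @return data.frame gene, induced, repressed, best_log2fc (signed log2FC
#'   of largest magnitude over flagged contrasts, NA if unflagged),
#'   best_contrast.
#' @export
regulated_in_model <- function(de_list, fc_threshold = 4,
                               fdr_threshold = 0.05) {
  if (!length(de_list)) stopf("no contrast tables supplied")
  lfc_min <- log2(fc_threshold)
  genes <- de_list[[1]]$gene
  for (nm in names(de_list)) {
    if (!identical(de_list[[nm]]$gene, genes))
      stopf("contrast table '%s' has a different gene set", nm)
  }
  induced <- repressed <- rep(FALSE, length(genes))
  best_lfc <- rep(NA_real_, length(genes))
  best_ctr <- rep(NA_character_, length(genes))
  for (nm in names(de_list)) {
    de <- de_list[[nm]]
    sig <- !is.na(de$fdr) & de$fdr < fdr_threshold
    up <- sig & de$log2FC >= lfc_min
    dn <- sig & de$log2FC <= -lfc_min
    induced <- induced | up
    repressed <- repressed | dn
    hit <- (up | dn) &
      (is.na(best_lfc) | abs(de$log2FC) > abs(best_lfc))
    best_lfc[hit] <- de$log2FC[hit]
    best_ctr[hit] <- nm
  }
  data.frame(gene = genes, induced = induced, repressed = repressed,
             best_log2fc = best_lfc, best_contrast = best_ctr,
             row.names = NULL)
}

#' Intersect per-model regulation flags into the common gene set
#'
#' Keeps genes induced in every model, plus genes repressed in every model.
#' Genes flagged in both directions within any model, or with conflicting
#' directions across models, are excluded (and reported).
#'
#' @param flags_list named list of [regulated_in_model()] outputs, one per
#'   model.
#' @return data.frame of class `hsc_common` with columns gene, direction,
#'   and one `log2fc_<model>` column per model (best flagged contrast);
#'   counts and ambiguous genes attached as attributes.
#' @export
intersect_common <- function(flags_list) {
  if (length(flags_list) < 2) stopf("need flags for at least two models")
  genes <- flags_list[[1]]$gene
  for (f in flags_list) {
    if (!identical(sort(f$gene), sort(genes)))
      stopf("models have different gene universes")
  }
  ind <- rep(TRUE, length(genes)); rep_ <- rep(TRUE, length(genes))
  ambiguous <- rep(FALSE, length(genes))
  for (f in flags_list) {
    f <- f[match(genes, f$gene), ]
    ind <- ind & f$induced
    rep_ <- rep_ & f$repressed
    ambiguous <- ambiguous | (f$induced & f$repressed)
  }
  keep_ind <- ind & !ambiguous
  keep_rep <- rep_ & !ambiguous
  sel <- keep_ind | keep_rep
  out <- data.frame(
    gene = genes[sel],
    direction = ifelse(keep_ind[sel], "induced", "repressed"),
    row.names = NULL
  )
  for (m in names(flags_list)) {
    f <- flags_list[[m]]
    out[[paste0("log2fc_", m)]] <- f$best_log2fc[match(out$gene, f$gene)]
  }
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) warnf("common gene set is empty")
  attr(out, "n_induced") <- sum(out$direction == "induced")
  attr(out, "n_repressed") <- sum(out$direction == "repressed")
  attr(out, "ambiguous") <- genes[ambiguous & (ind | rep_)]
  class(out) <- c("hsc_common", "data.frame")
  out
}
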