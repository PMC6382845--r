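# Motif-conditional induction statistics: motif-group assignment,
# fold-change comparisons with compact letter display, rank analysis,
# cluster x motif enrichment, and generic gene-set over-representation.

#' Partition genes by presence of two motifs
#'
#' Four-way partition of a gene set by ZOOPS presence of two motifs (e.g.
#' the ETS1 family and RUNX1, or ETS1 and AP-1): none, A-only, B-only,
#' both.
#'
#' @param genes character vector (e.g. the common gene set).
#' @param table an `hsc_motif_table` covering all `genes`.
#' @param motifs length-2 character: the presence columns to combine.
#' @return named factor over `genes` with levels none, `<A>_only`,
#'   `<B>_only`, both.
#' @export
assign_motif_groups <- function(genes, table,
                                motifs = c("ETS1_like", "RUNX1")) {
  stopifnot(inherits(table, "hsc_motif_table"), length(motifs) == 2)
  missing <- setdiff(genes, rownames(table$presence))
  if (length(missing))
    stopf("genes missing from the motif table: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  a <- table$presence[genes, motifs[1]] > 0
  b <- table$presence[genes, motifs[2]] > 0
  lev <- c("none", paste0(motifs[1], "_only"), paste0(motifs[2], "_only"),
           "both")
  grp <- ifelse(a & b, lev[4], ifelse(a, lev[2], ifelse(b, lev[3], lev[1])))
  factor(stats::setNames(grp, genes), levels = lev)
}

# Compact letters: connected components of the graph whose edges join
# group pairs that are NOT significantly different; groups sharing a
# letter are pairwise non-significant.
letter_components <- function(groups, pairs, alpha = 0.05) {
  comp <- stats::setNames(seq_along(groups), groups)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(pairs))) {
      if (!is.na(pairs$fdr[i]) && pairs$fdr[i] >= alpha) {
        a <- comp[[pairs$group1[i]]]; b <- comp[[pairs$group2[i]]]
        if (a != b) { comp[comp == b] <- a; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  letters[match(comp, sort(unique(comp)))]
}

#' Compare induction between motif groups
#'
#' Pairwise two-sided Wilcoxon rank-sum tests (exact up to 50 per group,
#' normal approximation with continuity correction beyond) on log2 fold
#' changes, BH-corrected across pairs, with per-group medians and a
#' compact letter display: groups not sharing a letter differ at
#' FDR < alpha.
#'
#' @param log2fc named numeric vector of per-gene log2 fold changes.
#' @param groups factor over the same genes (e.g. from
#'   [assign_motif_groups()]); empty groups are dropped with a warning.
#' @param alpha significance level for the letter display (default 0.05).
#' @return list with `groups` (data.frame: group, n, median, letter) and
#'   `pairs` (data.frame: group1, group2, p, fdr).
#' @export
compare_groups <- function(log2fc, groups, alpha = 0.05) {
  if (!is.null(names(log2fc)) && !is.null(names(groups)))
    groups <- groups[names(log2fc)]
  if (length(log2fc) != length(groups)) stopf("lengths differ")
  keep <- !is.na(groups) & !is.na(log2fc)
  log2fc <- log2fc[keep]; groups <- droplevels(factor(groups[keep]))
  sizes <- table(groups)
  if (any(sizes == 0)) {
    warnf("dropping empty group(s): %s",
          paste(names(sizes)[sizes == 0], collapse = ", "))
    groups <- droplevels(groups)
  }
  lev <- levels(groups)
  if (length(lev) < 2) stopf("need at least two non-empty groups")
  med <- vapply(lev, function(g) stats::median(log2fc[groups == g]),
                numeric(1))
  combos <- utils::combn(lev, 2)
  p <- apply(combos, 2, function(pr) {
    rank_sum_test(log2fc[groups == pr[1]], log2fc[groups == pr[2]])$p.value
  })
  pairs <- data.frame(group1 = combos[1, ], group2 = combos[2, ],
                      p = p, fdr = bh_adjust(p), row.names = NULL)
  grp <- data.frame(group = lev, n = as.integer(table(groups)[lev]),
                    median = med,
                    letter = letter_components(lev, pairs, alpha),
                    row.names = NULL)
  list(groups = grp, pairs = pairs)
}

#' Median induction rank per motif group
#'
#' Ranks genes by log2FC in descending order (rank 1 = most induced,
#' average ranks on ties) and reports the median rank of each group.
#'
#' @inheritParams compare_groups
#' @return data.frame: group, n, median_rank.
#' @export
rank_analysis <- function(log2fc, groups) {
  if (!is.null(names(log2fc)) && !is.null(names(groups)))
    groups <- groups[names(log2fc)]
  keep <- !is.na(groups) & !is.na(log2fc)
  log2fc <- log2fc[keep]; groups <- droplevels(factor(groups[keep]))
  r <- rank(-log2fc, ties.method = "average")
  lev <- levels(groups)
  data.frame(group = lev,
             n = as.integer(table(groups)[lev]),
             median_rank = vapply(lev, function(g)
               stats::median(r[groups == g]), numeric(1)),
             row.names = NULL)
}

#' Cluster x motif enrichment
#'
#' Tabulates, for every cluster (including "no cluster" for genes dropped
#' by the fit filter) and every motif gene set, the overlap count, the
#' enrichment ratio (count / cluster size) / (motif total / universe), and
#' the upper-tail hypergeometric probability of the overlap.
#'
#' @param assignment named character vector gene -> cluster label covering
#'   the universe ("no cluster" allowed as a label).
#' @param motif_sets named list of gene vectors (genes carrying each
#'   motif); intersected with the universe.
#' @param universe gene universe (default: names of `assignment`).
#' @return data.frame: cluster, motif, cluster_n, motif_n, count, ratio, p.
#' @export
cluster_motif_enrichment <- function(assignment, motif_sets,
                                     universe = names(assignment)) {
  assignment <- assignment[universe]
  if (any(is.na(assignment))) stopf("assignment must cover the universe")
  n_u <- length(universe)
  clusters <- sort(unique(as.character(assignment)))
  rows <- list()
  for (m in names(motif_sets)) {
    mg <- intersect(motif_sets[[m]], universe)
    for (cl in clusters) {
      cg <- universe[assignment == cl]
      cnt <- length(intersect(cg, mg))
      ratio <- if (length(cg) && length(mg))
        (cnt / length(cg)) / (length(mg) / n_u) else 0
      p <- overlap_significance(length(cg), length(mg), cnt, n_u)
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, motif = m, cluster_n = length(cg),
        motif_n = length(mg), count = cnt, ratio = ratio, p = p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a GMT gene-set collection
#'
#' @param path tab-separated GMT file: set name, description, member genes.
#' @return named list of character vectors; descriptions in attribute
#'   `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) < 3)
  if (length(bad)) stopf("GMT line(s) with fewer than 3 fields: %s",
                         paste(utils::head(bad, 5), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2)
  sets
}

#' Gene-set over-representation analysis
#'
#' Restricts the foreground (and the background) to robustly expressed
#' genes (RPKM at or above `rpkm_floor` in at least one column of `rpkm`,
#' when supplied), then tests each gene set by upper-tail hypergeometric
#' against the expressed background, BH-corrects across sets, and flags
#' sets with FDR at or below `fdr_max`. Optionally reports the median
#' log2FC of each set's foreground members for a chosen contrast.
#'
#' @param foreground,background character gene vectors (foreground must be
#'   contained in the background).
#' @param sets named list of gene sets (e.g. from [read_gmt()]).
#' @param rpkm optional gene x column RPKM matrix used for the expression
#'   filter (columns typically time-point averages across all models).
#' @param rpkm_floor expression floor, inclusive (default 10).
#' @param fdr_max enrichment call threshold (default 0.01).
#' @param log2fc optional named log2FC vector for the median summary.
#' @return data.frame: set, set_n, foreground_n, overlap, p, fdr,
#'   enriched, median_log2fc.
#' @export
ora <- function(foreground, background, sets, rpkm = NULL, rpkm_floor = 10,
                fdr_max = 0.01, log2fc = NULL) {
  if (!all(foreground %in% background))
    stopf("foreground must be contained in the background")
  if (!is.null(rpkm)) {
    expressed <- rownames(rpkm)[apply(rpkm, 1, max) >= rpkm_floor]
    background <- intersect(background, expressed)
    foreground <- intersect(foreground, expressed)
  }
  if (!length(foreground)) {
    warnf("empty foreground after expression filtering")
    return(data.frame(set = character(), set_n = integer(),
                      foreground_n = integer(), overlap = integer(),
                      p = numeric(), fdr = numeric(), enriched = logical(),
                      median_log2fc = numeric()))
  }
  n_b <- length(background); n_f <- length(foreground)
  res <- lapply(names(sets), function(s) {
    sg <- intersect(sets[[s]], background)
    ov <- intersect(sg, foreground)
    p <- stats::phyper(length(ov) - 1, length(sg), n_b - length(sg), n_f,
                       lower.tail = FALSE)
    med <- if (!is.null(log2fc) && length(ov))
      stats::median(log2fc[ov], na.rm = TRUE) else NA_real_
    data.frame(set = s, set_n = length(sg), foreground_n = n_f,
               overlap = length(ov), p = p, median_log2fc = med)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_adjust(out$p)
  out$enriched <- !is.na(out$fdr) & out$fdr <= fdr_max
  rownames(out) <- NULL
  out[, c("set", "set_n", "foreground_n", "overlap", "p", "fdr",
          "enriched", "median_log2fc")]
}
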