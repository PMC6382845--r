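# Promoter motif analysis: JASPAR-format PWM ingestion, strand-aware
# proximal-promoter extraction, both-strand log-odds scanning, ZOOPS
# gene x motif tables, hypergeometric enrichment, and motif spacing.

DNA_BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix from base counts
#'
#' Counts receive a total pseudocount distributed by the background
#' composition; probabilities are converted to base-2 log-odds against the
#' background.
#'
#' @param counts 4 x w numeric matrix of base counts, rows A, C, G, T.
#' @param id motif identifier.
#' @param name optional display name (defaults to `id`).
#' @param bg background base composition (default uniform 0.25).
#' @param pseudocount total pseudocount per column, split by `bg`
#'   (default 0.8).
#' @return object of class `hsc_pwm`: list with `id`, `name`, `width`,
#'   `counts`, `prob`, `logodds` (bits), `max_score`, `bg`.
#' @export
make_pwm <- function(counts, id, name = id, bg = rep(0.25, 4),
                     pseudocount = 0.8) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stopf("PWM counts must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 4) stopf("PWM width must be >= 4")
  if (any(counts < 0)) stopf("PWM counts must be non-negative")
  if (abs(sum(bg) - 1) > 1e-9) stopf("background must sum to 1")
  rownames(counts) <- DNA_BASES
  tot <- colSums(counts)
  prob <- sweep(counts + pseudocount * bg, 2, tot + pseudocount, "/")
  logodds <- log2(prob / bg)
  structure(
    list(id = id, name = name, width = ncol(counts), counts = counts,
         prob = prob, logodds = logodds,
         max_score = sum(apply(logodds, 2, max)), bg = bg),
    class = "hsc_pwm"
  )
}

#' Read PWMs from a JASPAR-format text file
#'
#' Accepts the JASPAR 2016 layout: a `>ID NAME` header followed by four
#' rows of counts, either bare numbers or `A [ 1 2 3 ]` style.
#'
#' @param path file with one or more JASPAR records.
#' @inheritParams make_pwm
#' @return named list of `hsc_pwm` objects.
#' @export
read_pwm <- function(path, bg = rep(0.25, 4), pseudocount = 0.8) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stopf("no JASPAR records in '%s'", path)
  out <- list()
  bounds <- c(heads, length(lines) + 1)
  for (i in seq_along(heads)) {
    header <- sub("^>\\s*", "", lines[heads[i]])
    toks <- strsplit(header, "\\s+")[[1]]
    id <- toks[1]
    name <- if (length(toks) > 1) toks[2] else id
    body <- lines[seq(heads[i] + 1, bounds[i + 1] - 1)]
    if (length(body) != 4)
      stopf("record '%s': expected 4 count rows, found %d", id, length(body))
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("\\[|\\]", " ", l)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
      if (any(is.na(vals))) stopf("record '%s': non-numeric counts", id)
      vals
    })
    if (length(unique(lengths(rows))) != 1)
      stopf("record '%s': ragged count rows", id)
    out[[id]] <- make_pwm(do.call(rbind, rows), id = id, name = name,
                          bg = bg, pseudocount = pseudocount)
  }
  out
}

#' Write PWMs to a JASPAR-format text file
#' @param pwms list of `hsc_pwm` objects.
#' @param path output file.
#' @export
write_pwm <- function(pwms, path) {
  if (inherits(pwms, "hsc_pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$id, p$name), con)
    for (b in DNA_BASES) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$counts[b, ], trim = TRUE),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read the 6-column gene annotation table
#'
#' Columns: gene_id, chrom, strand (+/-), tss_0based, length_bp,
#' planted_cluster (NA for real data).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, colClasses = c(
    gene_id = "character", chrom = "character", strand = "character"))
  need <- c("gene_id", "chrom", "strand", "tss_0based", "length_bp")
  if (!all(need %in% names(ann)))
    stopf("annotation must have columns: %s", paste(need, collapse = ", "))
  ann
}

#' Extract proximal promoters around annotated TSSs
#'
#' The window is (-upstream, +downstream) relative to the TSS in
#' transcription orientation: on the plus strand the half-open genomic
#' interval `[tss - upstream, tss + downstream)`; on the minus strand
#' `[tss - downstream + 1, tss + upstream + 1)` reverse-complemented. TSS
#' coordinates are 0-based. Genes whose window runs off the contig are
#' excluded and reported; sequences that are mostly N are flagged.
#'
#' @param genome a [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param annotation data.frame as from [read_annotation()].
#' @param upstream,downstream window extent in bp (defaults 300 and 50).
#' @return object of class `hsc_promoters`: list with `seqs`
#'   (DNAStringSet named by gene, all of width upstream + downstream),
#'   `coords` (per-gene genomic provenance), `excluded`, `flagged_n`.
#' @export
extract_promoters <- function(genome, annotation, upstream = 300,
                              downstream = 50) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  width <- upstream + downstream
  bad <- setdiff(unique(annotation$chrom), names(genome))
  if (length(bad)) stopf("unknown contig(s): %s", paste(bad, collapse = ", "))
  clen <- Biostrings::width(genome)[match(annotation$chrom, names(genome))]
  plus <- annotation$strand == "+"
  start0 <- ifelse(plus, annotation$tss_0based - upstream,
                   annotation$tss_0based - downstream + 1)
  end0 <- start0 + width  # half-open
  ok <- start0 >= 0 & end0 <= clen
  excluded <- annotation$gene_id[!ok]
  if (length(excluded))
    message(length(excluded), " gene(s) excluded: promoter window outside contig")
  ann <- annotation[ok, , drop = FALSE]
  s0 <- start0[ok]
  seqs <- Biostrings::subseq(genome[ann$chrom], start = s0 + 1,
                             width = width)
  minus <- ann$strand == "-"
  if (any(minus))
    seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  names(seqs) <- ann$gene_id
  nfrac <- Biostrings::letterFrequency(seqs, "N") / width
  flagged <- ann$gene_id[nfrac > 0.5]
  structure(
    list(seqs = seqs,
         coords = data.frame(gene_id = ann$gene_id, chrom = ann$chrom,
                             start0 = s0, end0 = s0 + width,
                             strand = ann$strand, row.names = NULL),
         excluded = excluded, flagged_n = flagged),
    class = "hsc_promoters"
  )
}

# Encode equal-width sequences as an integer matrix (A=1..T=4, else NA).
encode_seq_matrix <- function(seqs) {
  chars <- as.matrix(seqs)
  codes <- matrix(match(chars, DNA_BASES), nrow = nrow(chars))
  rownames(codes) <- names(seqs)
  codes
}

# Score every window of every (equal-width) sequence against one strand of
# a PWM. Returns an n_seq x n_window score matrix; windows containing
# non-ACGT bases score NA.
score_windows <- function(codes, logodds) {
  w <- ncol(logodds)
  L <- ncol(codes)
  nwin <- L - w + 1
  scores <- matrix(0, nrow(codes), nwin)
  for (i in seq_len(w)) {
    col <- logodds[, i]
    scores <- scores + matrix(col[codes[, i:(i + nwin - 1), drop = FALSE]],
                              nrow(codes))
  }
  scores
}

#' Scan promoters with PWMs on both strands
#'
#' Slides each PWM over both strands of every promoter and reports every
#' window whose log-odds score reaches `threshold_frac` times the PWM's
#' maximum achievable score. Positions are 0-based starts on the forward
#' promoter coordinate regardless of strand. Windows containing N are
#' skipped.
#'
#' @param pwms list of `hsc_pwm` objects (or a single one).
#' @param promoters an `hsc_promoters` object or named
#'   [Biostrings::DNAStringSet] of equal-width sequences.
#' @param threshold_frac per-site calling threshold as a fraction of the
#'   maximum achievable score (default 0.80).
#' @return data.frame with columns gene, pwm, start (0-based), strand,
#'   score.
#' @export
scan_pwm <- function(pwms, promoters, threshold_frac = 0.80) {
  if (inherits(pwms, "hsc_pwm")) pwms <- stats::setNames(list(pwms), pwms$id)
  seqs <- if (inherits(promoters, "hsc_promoters")) promoters$seqs
          else promoters
  if (length(unique(Biostrings::width(seqs))) != 1)
    stopf("promoter sequences must have equal width")
  L <- Biostrings::width(seqs)[1]
  codes_fwd <- encode_seq_matrix(seqs)
  codes_rev <- encode_seq_matrix(Biostrings::reverseComplement(seqs))
  res <- list()
  for (p in pwms) {
    if (p$width > L) stopf("PWM '%s' wider than the promoter window", p$id)
    if (p$max_score <= 0) stopf("PWM '%s' has non-positive max score", p$id)
    thr <- threshold_frac * p$max_score
    for (strand in c("+", "-")) {
      codes <- if (strand == "+") codes_fwd else codes_rev
      sc <- score_windows(codes, p$logodds)
      hit <- which(!is.na(sc) & sc >= thr - 1e-9, arr.ind = TRUE)
      if (!nrow(hit)) next
      pos <- hit[, 2] - 1L
      # map reverse-scan positions back to forward coordinates
      if (strand == "-") pos <- L - p$width - pos
      res[[length(res) + 1]] <- data.frame(
        gene = rownames(codes)[hit[, 1]], pwm = p$id, start = pos,
        strand = strand, score = sc[hit], row.names = NULL)
    }
  }
  if (!length(res)) {
    return(data.frame(gene = character(), pwm = character(),
                      start = integer(), strand = character(),
                      score = numeric()))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$gene, out$pwm, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the gene x motif ZOOPS table
#'
#' Binarizes hits per gene and PWM (present iff at least one hit) and
#' optionally collapses PWM families by OR (e.g. any of several ETS-family
#' PWMs counts as "ETS1_like"). Genes without any hit keep all-zero rows.
#'
#' @param hits data.frame from [scan_pwm()].
#' @param genes character vector: the full gene universe for the table.
#' @param pwm_ids PWM identifiers to tabulate (defaults to those in
#'   `hits`).
#' @param families named list mapping family name -> member PWM ids.
#' @return object of class `hsc_motif_table`: list with `presence` (0/1
#'   gene x motif matrix including family columns), `count`, `best`
#'   (best score, NA when absent), `hits`.
#' @export
gene_motif_table <- function(hits, genes, pwm_ids = NULL, families = list()) {
  if (is.null(pwm_ids)) pwm_ids <- sort(unique(hits$pwm))
  count <- matrix(0L, length(genes), length(pwm_ids),
                  dimnames = list(genes, pwm_ids))
  best <- matrix(NA_real_, length(genes), length(pwm_ids),
                 dimnames = list(genes, pwm_ids))
  h <- hits[hits$gene %in% genes & hits$pwm %in% pwm_ids, , drop = FALSE]
  if (nrow(h)) {
    tab <- table(factor(h$gene, levels = genes),
                 factor(h$pwm, levels = pwm_ids))
    count[] <- as.integer(tab)
    agg <- stats::aggregate(score ~ gene + pwm, data = h, FUN = max)
    best[cbind(match(agg$gene, genes), match(agg$pwm, pwm_ids))] <- agg$score
  }
  presence <- (count >= 1L) + 0L
  for (fam in names(families)) {
    members <- intersect(families[[fam]], pwm_ids)
    if (!length(members)) stopf("family '%s' has no scanned members", fam)
    presence <- cbind(presence,
                      (rowSums(presence[, members, drop = FALSE]) > 0) + 0L)
    colnames(presence)[ncol(presence)] <- fam
  }
  structure(list(presence = presence, count = count, best = best,
                 hits = hits, families = families),
            class = "hsc_motif_table")
}

#' ZOOPS hypergeometric motif enrichment
#'
#' Tests, per motif, whether the target genes carry the motif more often
#' than expected from the background frequency: upper-tail hypergeometric
#' with universe = background size, successes = background genes with the
#' motif, draws = target size. BH adjustment across motifs.
#'
#' @param target,background character gene vectors; targets must be a
#'   subset of the background.
#' @param table an `hsc_motif_table` covering the background genes.
#' @param motifs motif/family columns to test (default all).
#' @return data.frame: motif, target_n, target_hits, background_hits,
#'   fold, p, fdr.
#' @export
motif_enrichment <- function(target, background, table, motifs = NULL) {
  stopifnot(inherits(table, "hsc_motif_table"))
  if (!all(target %in% background)) stopf("targets must lie in the background")
  if (!all(background %in% rownames(table$presence)))
    stopf("motif table does not cover the background")
  if (is.null(motifs)) motifs <- colnames(table$presence)
  pres <- table$presence[background, motifs, drop = FALSE]
  in_target <- background %in% target
  K <- colSums(pres)                      # background genes with motif
  k <- colSums(pres[in_target, , drop = FALSE])  # target genes with motif
  n_t <- length(target); n_b <- length(background)
  p <- stats::phyper(k - 1, K, n_b - K, n_t, lower.tail = FALSE)
  fold <- (k / n_t) / (K / n_b)
  data.frame(motif = motifs, target_n = n_t, target_hits = as.integer(k),
             background_hits = as.integer(K), fold = fold, p = p,
             fdr = bh_adjust(p), row.names = NULL)
}

#' Mean spacing between two motifs in co-occupied promoters
#'
#' For every gene carrying at least one hit of each PWM, takes the minimal
#' midpoint-to-midpoint distance over hit pairs, then averages across
#' qualifying genes.
#'
#' @param hits data.frame from [scan_pwm()].
#' @param pwm_a,pwm_b `hsc_pwm` objects (their widths set the midpoints).
#' @return list with `mean_spacing` (NA and a flag if no gene qualifies),
#'   `per_gene` data.frame, `n`.
#' @export
motif_spacing <- function(hits, pwm_a, pwm_b) {
  ha <- hits[hits$pwm == pwm_a$id, , drop = FALSE]
  hb <- hits[hits$pwm == pwm_b$id, , drop = FALSE]
  genes <- intersect(unique(ha$gene), unique(hb$gene))
  if (!length(genes)) {
    return(list(mean_spacing = NA_real_, per_gene = NULL, n = 0L,
                undefined = TRUE))
  }
  sp <- vapply(genes, function(g) {
    ma <- ha$start[ha$gene == g] + pwm_a$width / 2
    mb <- hb$start[hb$gene == g] + pwm_b$width / 2
    min(abs(outer(ma, mb, "-")))
  }, numeric(1))
  list(mean_spacing = mean(sp),
       per_gene = data.frame(gene = genes, spacing = sp, row.names = NULL),
       n = length(genes), undefined = FALSE)
}

#' Position-frequency matrix of actual hit sequences
#'
#' Collects the promoter subsequences at every reported hit of one PWM
#' (reverse-complementing minus-strand hits) and tallies base frequencies
#' per position — the text-level equivalent of a motif logo built from
#' putative binding sites.
#'
#' @param hits data.frame from [scan_pwm()].
#' @param promoters `hsc_promoters` or named DNAStringSet.
#' @param pwm the `hsc_pwm` whose hits to collect.
#' @return 4 x width integer matrix of base counts (rows A, C, G, T).
#' @export
hit_pfm <- function(hits, promoters, pwm) {
  seqs <- if (inherits(promoters, "hsc_promoters")) promoters$seqs
          else promoters
  h <- hits[hits$pwm == pwm$id, , drop = FALSE]
  pfm <- matrix(0L, 4, pwm$width, dimnames = list(DNA_BASES, NULL))
  if (!nrow(h)) return(pfm)
  sub <- Biostrings::subseq(seqs[h$gene], start = h$start + 1,
                            width = pwm$width)
  minus <- h$strand == "-"
  if (any(minus)) sub[minus] <- Biostrings::reverseComplement(sub[minus])
  mat <- as.matrix(sub)
  for (j in seq_len(pwm$width)) {
    tb <- table(factor(mat[, j], levels = DNA_BASES))
    pfm[, j] <- pfm[, j] + as.integer(tb)
  }
  pfm
}
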