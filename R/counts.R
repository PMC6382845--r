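# Count container and normalization.
#
# Counts are held in a light list-based container (in the style of edgeR's
# DGEList): an integer gene x sample matrix plus a sample sheet carrying the
# experimental model, time point, and replicate for each column.

#' Construct a count matrix container
#'
#' @param counts integer matrix, genes x samples, with rownames (gene ids)
#'   and colnames (sample ids).
#' @param samples data.frame with one row per column of `counts` and columns
#'   `model` (character), `time` (numeric), `replicate` (integer).
#' @param lengths optional numeric vector of gene exonic lengths in bp, one
#'   per gene (required for RPKM).
#' @param libsize optional per-sample library sizes; defaults to column sums.
#' @return an object of class `hsc_counts`.
#' @export
count_matrix <- function(counts, samples, lengths = NULL, libsize = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stopf("counts must have gene ids as rownames")
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) stopf("counts must be integers")
  storage.mode(counts) <- "double"
  if (!is.data.frame(samples) || nrow(samples) != ncol(counts))
    stopf("samples must be a data.frame with one row per count column")
  need <- c("model", "time", "replicate")
  if (!all(need %in% names(samples)))
    stopf("samples must have columns: %s", paste(need, collapse = ", "))
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste(samples$model, samples$time, samples$replicate,
                              sep = "_")
  }
  rownames(samples) <- colnames(counts)
  if (is.null(libsize)) libsize <- colSums(counts)
  if (any(libsize <= 0)) stopf("library sizes must be positive")
  if (!is.null(lengths)) {
    if (length(lengths) != nrow(counts))
      stopf("lengths must have one entry per gene")
    if (any(lengths <= 0)) stopf("gene lengths must be positive")
    names(lengths) <- rownames(counts)
  }
  structure(
    list(counts = counts, samples = samples, lengths = lengths,
         libsize = libsize),
    class = "hsc_counts"
  )
}

#' @export
print.hsc_counts <- function(x, ...) {
  cat(sprintf("hsc_counts: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$model), collapse = ", ")))
  invisible(x)
}

#' Subset a count matrix container by sample
#' @param cm an `hsc_counts` object.
#' @param idx logical or integer sample index.
#' @return an `hsc_counts` restricted to the selected samples.
#' @export
subset_samples <- function(cm, idx) {
  count_matrix(cm$counts[, idx, drop = FALSE],
               cm$samples[idx, , drop = FALSE],
               lengths = cm$lengths,
               libsize = cm$libsize[idx])
}

#' Library-size normalization: CPM, log2-CPM, RPKM
#'
#' CPM is counts per million mapped reads; RPKM additionally divides by the
#' exonic length in kb. Log2 values use a prior count on the CPM scale so
#' zero counts map to finite values: log2(cpm + prior_count).
#'
#' @param cm an `hsc_counts` object.
#' @param prior_count prior, in CPM units, added before taking log2
#'   (default 0.5: a zero count at libsize 1e6 gives log2CPM = -1).
#' @return an object of class `hsc_norm` with matrices `cpm`, `log2cpm`,
#'   `rpkm`, `log2rpkm` (the RPKM matrices are NULL when gene lengths are
#'   absent), plus the sample sheet.
#' @export
normalize_counts <- function(cm, prior_count = 0.5) {
  stopifnot(inherits(cm, "hsc_counts"))
  if (prior_count <= 0) stopf("prior_count must be positive")
  cpm <- sweep(cm$counts, 2, cm$libsize / 1e6, "/")
  log2cpm <- log2(cpm + prior_count)
  rpkm <- log2rpkm <- NULL
  if (!is.null(cm$lengths)) {
    rpkm <- cpm / (cm$lengths / 1000)
    log2rpkm <- log2(rpkm + prior_count)
  }
  structure(
    list(cpm = cpm, log2cpm = log2cpm, rpkm = rpkm, log2rpkm = log2rpkm,
         samples = cm$samples, prior_count = prior_count),
    class = "hsc_norm"
  )
}

#' Per-time-point average expression for one model
#'
#' @param norm an `hsc_norm` object.
#' @param model model label to average within.
#' @param value which matrix to average: "rpkm", "cpm", "log2cpm", "log2rpkm".
#' @return gene x timepoint matrix of replicate averages, columns ordered by
#'   time.
#' @export
timepoint_means <- function(norm, model, value = c("rpkm", "cpm", "log2cpm",
                                                   "log2rpkm")) {
  value <- match.arg(value)
  mat <- norm[[value]]
  if (is.null(mat)) stopf("'%s' not available (gene lengths missing?)", value)
  sel <- norm$samples$model == model
  if (!any(sel)) stopf("no samples for model '%s'", model)
  times <- sort(unique(norm$samples$time[sel]))
  out <- vapply(times, function(tt) {
    rowMeans(mat[, sel & norm$samples$time == tt, drop = FALSE])
  }, numeric(nrow(mat)))
  colnames(out) <- as.character(times)
  out
}

#' Read a gene x sample count table with sample sheet from TSV files
#'
#' @param counts_file TSV with gene ids in the first column and one column
#'   per sample.
#' @param samples_file TSV with columns sample, model, time, replicate and
#'   optionally libsize (used as the normalization library size when
#'   present; otherwise column sums are used).
#' @param annotation optional annotation data.frame (as read by
#'   [read_annotation()]) supplying gene lengths.
#' @return an `hsc_counts` object.
#' @export
read_counts_tsv <- function(counts_file, samples_file, annotation = NULL) {
  tab <- utils::read.delim(counts_file, check.names = FALSE)
  genes <- as.character(tab[[1]])
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- genes
  samples <- utils::read.delim(samples_file)
  if ("sample" %in% names(samples)) {
    counts <- counts[, as.character(samples$sample), drop = FALSE]
  }
  lengths <- NULL
  if (!is.null(annotation)) {
    lengths <- annotation$length_bp[match(genes, annotation$gene_id)]
  }
  count_matrix(counts, samples[setdiff(names(samples), "libsize")],
               lengths = lengths, libsize = samples$libsize)
}

#' Write a count matrix container to TSV
#' @param cm an `hsc_counts` object.
#' @param counts_file,samples_file output paths.
#' @export
write_counts_tsv <- function(cm, counts_file, samples_file) {
  tab <- data.frame(gene = rownames(cm$counts), cm$counts,
                    check.names = FALSE)
  utils::write.table(tab, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sdf <- data.frame(sample = rownames(cm$samples), cm$samples,
                    libsize = cm$libsize, row.names = NULL)
  utils::write.table(sdf, samples_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_file, samples_file))
}
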