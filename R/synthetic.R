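# Synthetic-data generator with planted truth.
#
# Emulates the three HSC activation experiments — Western diet (WD, weeks
# 0/12/16/24), carbon tetrachloride (CCl4, weeks 0/1/4/8), and in vitro
# transdifferentiation (IVT, days 0/1/4/8/12) — as NB-distributed counts
# with gene-wise baseline means, a common dispersion, planted temporal
# profile clusters (including a strongly induced and a strongly repressed
# program), and promoter sequences in which ETS1/RUNX1/AP-1 motif presence
# is statistically coupled to induction magnitude. Everything planted is
# recorded, so each pipeline stage can be verified against ground truth.

#' Default planted temporal profile shapes
#'
#' Six prototype shapes on a common unit-time grid, each with its own
#' log2FC amplitude: a strongly repressed program (`cluster1`), transient
#' down, late up, early saturating up, transient up, and a strongly induced
#' linear program (`cluster6`). Shapes are specified on the scaled axis and
#' converted to log2FC trajectories by the amplitude.
#'
#' @return list with `shapes` (profile x gridpoint matrix, grid on
#'   `[0, 1]`) and `amplitudes` (named numeric, log2FC at full deflection).
#' @export
default_profiles <- function() {
  u <- seq(0, 1, length.out = 9)
  shapes <- rbind(
    cluster1 = -u^0.8,
    cluster2 = -sin(pi * u),
    cluster3 = u^4,
    cluster4 = 1 - (1 - u)^3,
    cluster5 = sin(pi * u),
    cluster6 = u
  )
  colnames(shapes) <- format(u, digits = 3)
  list(shapes = shapes,
       amplitudes = c(cluster1 = 3, cluster2 = 2, cluster3 = 2.5,
                      cluster4 = 2.5, cluster5 = 2, cluster6 = 4))
}

# Count matrix for a consensus with optional degenerate (two-base) columns.
pwm_counts_from_consensus <- function(consensus, degenerate = integer(0),
                                      alt = character(0)) {
  bases <- strsplit(consensus, "")[[1]]
  w <- length(bases)
  counts <- matrix(1, 4, w, dimnames = list(DNA_BASES, NULL))
  for (j in seq_len(w)) counts[bases[j], j] <- 97
  for (i in seq_along(degenerate)) {
    j <- degenerate[i]
    counts[, j] <- 1
    counts[bases[j], j] <- 50
    counts[alt[i], j] <- 48
  }
  counts
}

#' Default synthetic PWM collection
#'
#' Six motif models: ETS1 plus three further ETS-family PWMs sharing the
#' GGAA(G/T) core (collapsed downstream into the `ETS1_like` family),
#' RUNX1, and AP1. Each has one two-base degenerate column and otherwise
#' sharp columns, giving high-information motifs whose 80%-of-max calling
#' threshold admits the degenerate variants but no other mismatch.
#'
#' @inheritParams make_pwm
#' @return named list of `hsc_pwm` objects.
#' @export
default_pwms <- function(bg = rep(0.25, 4), pseudocount = 0.8) {
  spec <- list(
    ETS1  = list("ACAGGAAGTG", 10, "A"),
    ELK1  = list("CCGGAAGTG",   9, "A"),
    ELK3  = list("AGCGGAAGT",   9, "C"),
    ETV5  = list("TCCGGAAGC",   9, "T"),
    RUNX1 = list("TGTGGTTTG",   9, "A"),
    AP1   = list("TGACTCATC",   9, "T")
  )
  out <- list()
  for (id in names(spec)) {
    s <- spec[[id]]
    out[[id]] <- make_pwm(
      pwm_counts_from_consensus(s[[1]], degenerate = s[[2]], alt = s[[3]]),
      id = id, bg = bg, pseudocount = pseudocount)
  }
  out
}

#' Default ETS-family collapsing for ZOOPS tables
#' @return named list mapping family name to member PWM ids.
#' @export
default_motif_families <- function() {
  list(ETS1_like = c("ETS1", "ELK1", "ELK3", "ETV5"))
}

#' Synthetic study configuration
#'
#' Defaults reflect the emulated study design: three models with their time
#' courses, 3 replicates per point, NB counts with common dispersion 0.1,
#' log-normal baseline means (log2 mean 5, sd 2), six planted profile
#' clusters, and motif placement coupled to the induced program.
#'
#' @param n_genes number of genes (default 5000).
#' @param models named list of time-point vectors per model.
#' @param replicates replicates per time point (3-4; default 3).
#' @param dispersion common NB dispersion phi >= 0 (default 0.1).
#' @param baseline_log2_mean,baseline_log2_sd location and scale of
#'   baseline expression: means are 2^Normal(mean, sd) in CPM-like units.
#' @param frac_regulated fraction of genes carrying a planted profile
#'   (default 0.3; the rest are null genes).
#' @param profiles planted profile shapes and amplitudes
#'   ([default_profiles()]).
#' @param cluster_proportions simplex weights over the planted profiles.
#' @param induced_cluster,repressed_cluster names of the strongly induced
#'   and repressed programs.
#' @param motif_coupling probability that an induced-cluster gene receives
#'   a dual ETS1 + RUNX1 placement (default 0.6).
#' @param p_single_induced per-motif probability of a lone ETS1 or RUNX1
#'   placement in induced-cluster genes not given the dual placement.
#' @param p_background named background placement probabilities
#'   (ETS1, RUNX1, AP1) for all other genes.
#' @param p_ap1_induced AP1 placement probability in induced-cluster genes.
#' @param dual_shift extra log2FC (at the final time point, ramped over the
#'   ordinal time axis) added to regulated genes carrying both ETS1 and
#'   RUNX1 — the planted motif/induction coupling (default 2).
#' @param promoter_len promoter window length in bp (default 350,
#'   i.e. -300/+50).
#' @param site_threshold planted sites are sampled from the PWM conditioned
#'   on scoring at least this fraction of the maximum (default 0.80,
#'   matching the scanner's default calling threshold).
#' @param lib_range library-size range, uniform (default 0.8e6-1.2e6 so
#'   CPM roughly equals counts).
#' @param genes_per_contig genes tiled per synthetic contig (default 100).
#' @param flank bp of flank on each side of a TSS slot (default 2000).
#' @param pwms PWM collection to plant and write ([default_pwms()]).
#' @param seed master seed.
#' @return validated config list of class `hsc_config`.
#' @export
synthetic_config <- function(
    n_genes = 5000,
    models = list(WD = c(0, 12, 16, 24), CCl4 = c(0, 1, 4, 8),
                  IVT = c(0, 1, 4, 8, 12)),
    replicates = 3,
    dispersion = 0.1,
    baseline_log2_mean = 5, baseline_log2_sd = 2,
    frac_regulated = 0.3,
    profiles = default_profiles(),
    cluster_proportions = c(cluster1 = 0.22, cluster2 = 0.12,
                            cluster3 = 0.14, cluster4 = 0.14,
                            cluster5 = 0.13, cluster6 = 0.25),
    induced_cluster = "cluster6", repressed_cluster = "cluster1",
    motif_coupling = 0.6, p_single_induced = 0.15,
    p_background = c(ETS1 = 0.12, RUNX1 = 0.05, AP1 = 0.10),
    p_ap1_induced = 0.30,
    dual_shift = 2,
    promoter_len = 350,
    site_threshold = 0.80,
    lib_range = c(0.8e6, 1.2e6),
    genes_per_contig = 100,
    flank = 2000,
    pwms = default_pwms(),
    seed = 1) {
  if (abs(sum(cluster_proportions) - 1) > 1e-12)
    stopf("cluster_proportions must sum to 1")
  if (!setequal(names(cluster_proportions), rownames(profiles$shapes)))
    stopf("cluster_proportions must name every planted profile")
  if (dispersion < 0) stopf("dispersion must be >= 0")
  if (replicates < 2) stopf("need at least 2 replicates")
  max_w <- max(vapply(pwms, function(p) p$width, numeric(1)))
  if (promoter_len < max_w)
    stopf("promoter_len (%d) shorter than the widest PWM (%d)",
          promoter_len, max_w)
  if (!all(c("ETS1", "RUNX1", "AP1") %in% names(pwms)))
    stopf("pwms must include ETS1, RUNX1 and AP1")
  cfg <- list(
    n_genes = n_genes, models = models, replicates = replicates,
    dispersion = dispersion, baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd, frac_regulated = frac_regulated,
    profiles = profiles, cluster_proportions = cluster_proportions,
    induced_cluster = induced_cluster, repressed_cluster = repressed_cluster,
    motif_coupling = motif_coupling, p_single_induced = p_single_induced,
    p_background = p_background, p_ap1_induced = p_ap1_induced,
    dual_shift = dual_shift, promoter_len = promoter_len,
    site_threshold = site_threshold, lib_range = lib_range,
    genes_per_contig = genes_per_contig, flank = flank, pwms = pwms,
    seed = as.integer(seed))
  class(cfg) <- "hsc_config"
  cfg
}

# Sample a site from the PWM's column distributions, conditioned on scoring
# at least threshold_frac of the maximum (a planted, functional site).
sample_pwm_site <- function(pwm, threshold_frac = 0.80, max_tries = 200) {
  thr <- threshold_frac * pwm$max_score
  for (i in seq_len(max_tries)) {
    idx <- vapply(seq_len(pwm$width),
                  function(j) sample.int(4, 1, prob = pwm$prob[, j]),
                  integer(1))
    if (sum(pwm$logodds[cbind(idx, seq_len(pwm$width))]) >= thr - 1e-9)
      return(paste(DNA_BASES[idx], collapse = ""))
  }
  # fall back to the consensus, which always attains the maximum
  paste(DNA_BASES[apply(pwm$prob, 2, which.max)], collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

shape_at <- function(shape_row, u) {
  grid <- seq(0, 1, length.out = length(shape_row))
  stats::approx(grid, shape_row, xout = u)$y
}

#' Generate the planted truth for a synthetic study
#'
#' Assigns genes to planted profile clusters (or "null"), draws baseline
#' expression and gene geometry (contig, strand, TSS, exonic length),
#' derives the per-model log2FC trajectory of every gene, places motif
#' instances in promoters with the configured cluster/motif coupling, and
#' synthesizes the promoter sequences. Deterministic for a fixed seed.
#'
#' @param config an [synthetic_config()] object.
#' @return object of class `hsc_truth`: list with `genes` (annotation-style
#'   data.frame incl. planted cluster), `baseline`, `trajectories` (per
#'   model, gene x timepoint log2FC), `motifs` (gene, motif, pos, strand,
#'   site), `promoters` (DNAStringSet), `pwms`, `config`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "hsc_config"))
  set.seed(stage_seed(config$seed, 1))
  n <- config$n_genes
  gene_id <- sprintf("gene%05d", seq_len(n))

  cl_names <- rownames(config$profiles$shapes)
  regulated <- stats::runif(n) < config$frac_regulated
  cluster <- rep("null", n)
  cluster[regulated] <- sample(cl_names, sum(regulated), replace = TRUE,
                               prob = config$cluster_proportions[cl_names])

  baseline <- 2^stats::rnorm(n, config$baseline_log2_mean,
                             config$baseline_log2_sd)
  names(baseline) <- gene_id

  # geometry: genes tiled on contigs, one slot of 2*flank per gene
  slot <- 2 * config$flank
  contig_i <- (seq_len(n) - 1) %/% config$genes_per_contig + 1
  within <- (seq_len(n) - 1) %% config$genes_per_contig
  chrom <- sprintf("contig%03d", contig_i)
  tss <- within * slot + config$flank
  strand <- sample(c("+", "-"), n, replace = TRUE)
  length_bp <- pmax(200, round(stats::rlnorm(n, log(1500), 0.6)))

  genes <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                      tss_0based = tss, length_bp = length_bp,
                      planted_cluster = cluster, row.names = NULL)

  # motif presence, coupled to the induced program
  pw <- config$pwms
  has <- matrix(FALSE, n, 3, dimnames = list(gene_id,
                                             c("ETS1", "RUNX1", "AP1")))
  induced <- cluster == config$induced_cluster
  dual <- induced & stats::runif(n) < config$motif_coupling
  has[dual, c("ETS1", "RUNX1")] <- TRUE
  lone <- induced & !dual
  has[lone, "ETS1"] <- stats::runif(sum(lone)) < config$p_single_induced
  has[lone, "RUNX1"] <- stats::runif(sum(lone)) < config$p_single_induced
  other <- !induced
  for (m in c("ETS1", "RUNX1"))
    has[other, m] <- stats::runif(sum(other)) < config$p_background[[m]]
  has[, "AP1"] <- stats::runif(n) <
    ifelse(induced, config$p_ap1_induced, config$p_background[["AP1"]])

  # trajectories: amplitude * shape at the ordinal time grid, plus the
  # dual-motif induction shift for regulated dual-motif genes
  dual_now <- has[, "ETS1"] & has[, "RUNX1"] & cluster != "null"
  trajectories <- list()
  for (mdl in names(config$models)) {
    tp <- config$models[[mdl]]
    u <- if (length(tp) > 1) (seq_along(tp) - 1) / (length(tp) - 1) else 0
    traj <- matrix(0, n, length(tp),
                   dimnames = list(gene_id, as.character(tp)))
    for (cl in cl_names) {
      idx <- cluster == cl
      if (!any(idx)) next
      prof <- config$profiles$amplitudes[[cl]] *
        shape_at(config$profiles$shapes[cl, ], u)
      traj[idx, ] <- matrix(prof, sum(idx), length(tp), byrow = TRUE)
    }
    if (any(dual_now)) {
      traj[dual_now, ] <- traj[dual_now, , drop = FALSE] +
        matrix(config$dual_shift * u, sum(dual_now), length(tp),
               byrow = TRUE)
    }
    trajectories[[mdl]] <- traj
  }

  # promoters with planted, non-overlapping motif instances
  plen <- config$promoter_len
  motif_rows <- list()
  promoters <- character(n)
  for (i in seq_len(n)) {
    seq_chars <- sample(DNA_BASES, plen, replace = TRUE)
    occupied <- integer(0)
    for (m in c("ETS1", "RUNX1", "AP1")) {
      if (!has[i, m]) next
      w <- pw[[m]]$width
      pos <- NA_integer_
      for (try in 1:100) {
        cand <- sample.int(plen - w + 1, 1) - 1L  # 0-based
        if (!any((cand:(cand + w - 1)) %in% occupied)) { pos <- cand; break }
      }
      if (is.na(pos)) next  # promoter too crowded; skip this placement
      site <- sample_pwm_site(pw[[m]], config$site_threshold)
      site_strand <- sample(c("+", "-"), 1)
      written <- if (site_strand == "+") site else revcomp_chr(site)
      seq_chars[(pos + 1):(pos + w)] <- strsplit(written, "")[[1]]
      occupied <- c(occupied, pos:(pos + w - 1))
      motif_rows[[length(motif_rows) + 1]] <- data.frame(
        gene = gene_id[i], motif = m, pos = pos, strand = site_strand,
        site = site, row.names = NULL)
    }
    promoters[i] <- paste(seq_chars, collapse = "")
  }
  motifs <- if (length(motif_rows)) do.call(rbind, motif_rows) else
    data.frame(gene = character(), motif = character(), pos = integer(),
               strand = character(), site = character())
  prom <- Biostrings::DNAStringSet(promoters)
  names(prom) <- gene_id

  structure(
    list(genes = genes, baseline = baseline, trajectories = trajectories,
         motifs = motifs, promoters = prom, pwms = pw, config = config),
    class = "hsc_truth"
  )
}

#' Simulate NB counts for every model from planted truth
#'
#' Counts are NB with mean baseline * 2^log2FC(t) * libsize/1e6 and the
#' configured common dispersion (Poisson in the phi = 0 limit); library
#' sizes are drawn uniformly from the configured range. Deterministic for a
#' fixed seed.
#'
#' @param truth an [generate_truth()] result.
#' @param config configuration; defaults to the one inside `truth`.
#' @return named list of `hsc_counts`, one per model, with sample metadata
#'   (model, time, replicate) and gene lengths attached.
#' @export
simulate_counts <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "hsc_truth"))
  set.seed(stage_seed(config$seed, 2))
  n <- nrow(truth$genes)
  out <- list()
  for (mdl in names(config$models)) {
    tp <- config$models[[mdl]]
    nrep <- config$replicates
    nsamp <- length(tp) * nrep
    libsize <- stats::runif(nsamp, config$lib_range[1], config$lib_range[2])
    samples <- data.frame(
      model = mdl,
      time = rep(tp, each = nrep),
      replicate = rep(seq_len(nrep), length(tp)))
    mu <- truth$baseline *
      2^truth$trajectories[[mdl]][, rep(seq_along(tp), each = nrep)]
    mu <- sweep(mu, 2, libsize / 1e6, "*")
    counts <- if (config$dispersion == 0) {
      matrix(stats::rpois(n * nsamp, mu), n, nsamp)
    } else {
      matrix(stats::rnbinom(n * nsamp, size = 1 / config$dispersion,
                            mu = mu), n, nsamp)
    }
    rownames(counts) <- truth$genes$gene_id
    colnames(counts) <- sprintf("%s_t%s_r%d", mdl, samples$time,
                                samples$replicate)
    out[[mdl]] <- count_matrix(counts, samples,
                               lengths = truth$genes$length_bp,
                               libsize = libsize)
  }
  out
}

#' Write the synthetic genome, annotation, PWMs and truth tables
#'
#' Assembles one synthetic contig per block of genes (random sequence with
#' each gene's promoter content spliced in at its genomic location,
#' strand-aware), and writes: a multi-record genome FASTA (60-column
#' lines), the 6-column annotation TSV, the PWM collection in JASPAR text
#' format, and the planted-truth tables. Re-extracting promoters from the
#' written files recovers every planted motif instance at its recorded
#' position and strand.
#'
#' @param truth an [generate_truth()] result.
#' @param outdir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_genome_and_annotation <- function(truth, outdir) {
  stopifnot(inherits(truth, "hsc_truth"))
  config <- truth$config
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(stage_seed(config$seed, 3))
  genes <- truth$genes
  slot <- 2 * config$flank
  contigs <- unique(genes$chrom)
  contig_seqs <- character(length(contigs))
  up <- 300; down <- config$promoter_len - 300
  for (ci in seq_along(contigs)) {
    g <- genes[genes$chrom == contigs[ci], , drop = FALSE]
    clen <- nrow(g) * slot
    chars <- sample(DNA_BASES, clen, replace = TRUE)
    for (j in seq_len(nrow(g))) {
      pseq <- as.character(truth$promoters[[g$gene_id[j]]])
      tss <- g$tss_0based[j]
      if (g$strand[j] == "+") {
        s0 <- tss - up
        chars[(s0 + 1):(s0 + config$promoter_len)] <- strsplit(pseq, "")[[1]]
      } else {
        s0 <- tss - down + 1
        chars[(s0 + 1):(s0 + config$promoter_len)] <-
          strsplit(revcomp_chr(pseq), "")[[1]]
      }
    }
    contig_seqs[ci] <- paste(chars, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(contig_seqs)
  names(genome) <- contigs

  paths <- c(
    genome = file.path(outdir, "genome.fa"),
    annotation = file.path(outdir, "annotation.tsv"),
    pwms = file.path(outdir, "pwms.jaspar"),
    truth_genes = file.path(outdir, "truth_genes.tsv"),
    truth_motifs = file.path(outdir, "truth_motifs.tsv"))
  Biostrings::writeXStringSet(genome, paths[["genome"]], width = 60)
  utils::write.table(genes, paths[["annotation"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_pwm(truth$pwms, paths[["pwms"]])
  utils::write.table(genes[, c("gene_id", "planted_cluster")],
                     paths[["truth_genes"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth$motifs, paths[["truth_motifs"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (mdl in names(truth$trajectories)) {
    p <- file.path(outdir, sprintf("truth_trajectories_%s.tsv", mdl))
    tab <- data.frame(gene = rownames(truth$trajectories[[mdl]]),
                      truth$trajectories[[mdl]], check.names = FALSE)
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[paste0("trajectories_", mdl)]] <- p
  }
  invisible(paths)
}

#' Write a synthetic gene-set collection (GMT)
#'
#' One set per planted profile cluster (its member genes) plus random
#' decoy sets, in tab-separated GMT format.
#'
#' @param truth an [generate_truth()] result.
#' @param path output GMT path.
#' @param n_random number of random decoy sets (default 15).
#' @param set_size size of each decoy set (default 50).
#' @return the path, invisibly.
#' @export
write_synthetic_gmt <- function(truth, path, n_random = 15, set_size = 50) {
  stopifnot(inherits(truth, "hsc_truth"))
  set.seed(stage_seed(truth$config$seed, 4))
  con <- file(path, "w")
  on.exit(close(con))
  genes <- truth$genes
  for (cl in rownames(truth$config$profiles$shapes)) {
    members <- genes$gene_id[genes$planted_cluster == cl]
    if (!length(members)) next
    writeLines(paste(c(toupper(paste0("PROGRAM_", cl)),
                       sprintf("planted %s program", cl), members),
                     collapse = "\t"), con)
  }
  for (i in seq_len(n_random)) {
    members <- sample(genes$gene_id, set_size)
    writeLines(paste(c(sprintf("RANDOM_SET_%02d", i), "random decoy set",
                       members), collapse = "\t"), con)
  }
  invisible(path)
}
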