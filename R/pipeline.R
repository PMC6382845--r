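# End-to-end orchestration: synthetic generation (or user files) ->
# differential expression -> common genes -> clustering -> cluster matching
# -> promoter motif scanning -> induction statistics, with a
# machine-readable run report and deterministic TSV outputs.

#' Pipeline configuration
#'
#' @param synthetic an [synthetic_config()] for synthetic-mode runs, or
#'   NULL for file mode.
#' @param files named list for file mode: `counts`, `samples`,
#'   `annotation`, `genome`, `pwms`, optional `gmt`. Exactly one of
#'   `synthetic` / `files` must be given.
#' @param fc_threshold,fdr_threshold common-gene selection thresholds
#'   (defaults 4 and 0.05).
#' @param floor_log2cpm DE expression floor (default 2).
#' @param rpkm_floor ORA expression floor (default 10).
#' @param drop_frac clustering fit-filter fraction (default 0.10).
#' @param min_cluster_size post-hoc cluster-size threshold (default 20).
#' @param ora_fdr ORA enrichment threshold (default 0.01).
#' @param scan_threshold PWM calling threshold fraction (default 0.80).
#' @param cluster_models models to cluster and pair (default first two,
#'   i.e. the two in vivo models).
#' @param k_range candidate cluster counts (default 2:12).
#' @param motif_families PWM family collapsing
#'   ([default_motif_families()]).
#' @param group_motifs the two presence columns defining the motif groups
#'   (default ETS1 family and RUNX1).
#' @param seed master seed (used in file mode for any resampling; in
#'   synthetic mode the synthetic config's seed governs).
#' @return config list of class `hsc_run_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(), files = NULL,
                            fc_threshold = 4, fdr_threshold = 0.05,
                            floor_log2cpm = 2, rpkm_floor = 10,
                            drop_frac = 0.10, min_cluster_size = 20,
                            ora_fdr = 0.01, scan_threshold = 0.80,
                            cluster_models = NULL, k_range = 2:12,
                            motif_families = default_motif_families(),
                            group_motifs = c("ETS1_like", "RUNX1"),
                            seed = NULL) {
  if (is.null(synthetic) == is.null(files))
    stopf("exactly one input mode: synthetic or files")
  stopifnot(fc_threshold > 1, fdr_threshold > 0, fdr_threshold < 1,
            drop_frac >= 0, drop_frac < 1, scan_threshold > 0,
            scan_threshold <= 1, rpkm_floor >= 0, ora_fdr > 0, ora_fdr < 1)
  if (!is.null(files)) {
    need <- c("counts", "samples", "annotation", "genome", "pwms")
    miss <- setdiff(need, names(files))
    if (length(miss))
      stopf("file mode is missing input(s): %s", paste(miss, collapse = ", "))
    for (f in unlist(files[need]))
      if (!file.exists(f)) stopf("input file not found: %s", f)
  }
  structure(
    list(synthetic = synthetic, files = files,
         fc_threshold = fc_threshold, fdr_threshold = fdr_threshold,
         floor_log2cpm = floor_log2cpm, rpkm_floor = rpkm_floor,
         drop_frac = drop_frac, min_cluster_size = min_cluster_size,
         ora_fdr = ora_fdr, scan_threshold = scan_threshold,
         cluster_models = cluster_models, k_range = k_range,
         motif_families = motif_families, group_motifs = group_motifs,
         seed = seed %||% (if (!is.null(synthetic)) synthetic$seed else 1)),
    class = "hsc_run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML may contain a `synthetic:` block (scalar overrides of
#' [synthetic_config()] arguments) or a `files:` block, plus any scalar
#' [pipeline_config()] threshold.
#'
#' @param path YAML file.
#' @return an `hsc_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(y$synthetic)) {
    syn_args <- y$synthetic
    if (isTRUE(syn_args)) syn_args <- list()
    syn <- do.call(synthetic_config, syn_args)
  }
  args <- y[setdiff(names(y), "synthetic")]
  do.call(pipeline_config, c(list(synthetic = syn), args))
}

#' Run the full analysis pipeline
#'
#' Executes every stage and returns a run report plus all intermediate
#' results. In synthetic mode the genome, annotation and PWMs are written
#' to `workdir` and promoters are re-extracted from those files, so the
#' round trip through the on-disk formats is part of every run.
#'
#' @param config an [pipeline_config()] object.
#' @param workdir directory for the generated genome/annotation/PWM files
#'   (synthetic mode; default a tempdir subdirectory).
#' @return object of class `hsc_run`: list with `report` (flat summary),
#'   and full per-stage results (`truth`, `counts`, `de`, `common`,
#'   `clusters`, `pairing`, `shared`, `motifs`, `induction`).
#' @export
run_pipeline <- function(config, workdir = NULL) {
  stopifnot(inherits(config, "hsc_run_config"))
  report <- list(seed = config$seed)

  # --- stage 1: inputs (synthetic or files)
  if (!is.null(config$synthetic)) {
    truth <- generate_truth(config$synthetic)
    counts <- simulate_counts(truth)
    workdir <- workdir %||% file.path(tempdir(),
                                      sprintf("hsc_run_%d", config$seed))
    paths <- write_genome_and_annotation(truth, workdir)
    gmt_path <- file.path(workdir, "sets.gmt")
    write_synthetic_gmt(truth, gmt_path)
    annotation <- read_annotation(paths[["annotation"]])
    genome_path <- paths[["genome"]]
    pwms <- read_pwm(paths[["pwms"]])
  } else {
    truth <- NULL
    annotation <- read_annotation(config$files$annotation)
    cm_all <- read_counts_tsv(config$files$counts, config$files$samples,
                              annotation = annotation)
    counts <- lapply(split(seq_len(ncol(cm_all$counts)),
                           cm_all$samples$model),
                     function(ix) subset_samples(cm_all, ix))
    genome_path <- config$files$genome
    pwms <- read_pwm(config$files$pwms)
    gmt_path <- config$files$gmt
  }
  models <- names(counts)
  report$models <- models

  # --- stage 2: normalization + DE (all later-vs-earlier contrasts)
  norm <- lapply(counts, normalize_counts)
  phi <- lapply(counts, estimate_common_dispersion)
  de <- list()
  for (mdl in models) {
    de[[mdl]] <- model_contrasts(counts[[mdl]], mdl, phi = phi[[mdl]],
                                 floor_log2cpm = config$floor_log2cpm)
  }
  final_contrast <- vapply(de, function(x) names(x)[length(names(x))], "")
  de_counts <- list()
  shift <- list()
  for (mdl in models) {
    fin <- de[[mdl]][[final_contrast[[mdl]]]]
    sig <- !is.na(fin$fdr) & fin$fdr <= 0.05
    de_counts[[mdl]] <- c(induced = sum(sig & fin$log2FC > 0),
                          repressed = sum(sig & fin$log2FC < 0))
    tp <- sort(unique(counts[[mdl]]$samples$time))
    ctrl <- rowMeans(norm[[mdl]]$log2cpm[
      , counts[[mdl]]$samples$time == tp[1], drop = FALSE])
    act <- rowMeans(norm[[mdl]]$log2cpm[
      , counts[[mdl]]$samples$time == tp[length(tp)], drop = FALSE])
    shift[[mdl]] <- distribution_shift_test(ctrl, act)
  }
  report$phi <- unlist(phi)
  report$de_final <- de_counts
  report$shift_p <- vapply(shift, `[[`, numeric(1), "p.value")
  report$shift_direction <- vapply(shift, `[[`, character(1), "direction")

  # --- stage 3: common genes
  flags <- lapply(models, function(mdl)
    regulated_in_model(de[[mdl]], config$fc_threshold,
                       config$fdr_threshold))
  names(flags) <- models
  common <- intersect_common(flags)
  report$n_common <- nrow(common)
  report$n_common_induced <- attr(common, "n_induced")
  report$n_common_repressed <- attr(common, "n_repressed")

  # --- stage 4: clustering per model
  cluster_models <- config$cluster_models %||% models[seq_len(min(2,
                                                     length(models)))]
  clusters <- list()
  for (mdl in cluster_models) {
    avg <- timepoint_means(norm[[mdl]], mdl, "rpkm")[common$gene, ,
                                                     drop = FALSE]
    prof <- vst_scale(avg)
    k <- choose_k(prof, config$k_range)
    cs <- pam_cluster(prof, k)
    clusters[[mdl]] <- fit_filter(cs, config$drop_frac,
                                  config$min_cluster_size)
    report[[paste0("k_", mdl)]] <- clusters[[mdl]]$k
    report[[paste0("avg_fit_", mdl)]] <-
      cluster_prototypes(clusters[[mdl]])$avg_fit
  }

  # --- stage 5: cluster pairing + shared genes
  pairing <- shared <- NULL
  if (length(cluster_models) >= 2) {
    a <- cluster_models[1]; b <- cluster_models[2]
    pairing <- pair_clusters(clusters[[a]]$prototypes,
                             clusters[[b]]$prototypes)
    shared <- shared_genes(pairing, clusters[[a]]$assignment,
                           clusters[[b]]$assignment)
    # universe: genes retained by the fit filter in BOTH models; cluster
    # sizes restricted to it so the hypergeometric margins are consistent
    uni_genes <- intersect(names(clusters[[a]]$assignment),
                           names(clusters[[b]]$assignment))
    universe <- length(uni_genes)
    aa <- clusters[[a]]$assignment[uni_genes]
    bb <- clusters[[b]]$assignment[uni_genes]
    shared$p <- vapply(seq_len(nrow(shared)), function(i)
      overlap_significance(sum(as.character(aa) == shared$a[i]),
                           sum(as.character(bb) == shared$b[i]),
                           shared$shared_n[i], universe), numeric(1))
    report$pairing_r <- stats::setNames(pairing$r,
                                        paste(pairing$a, pairing$b,
                                              sep = ":"))
    report$n_shared <- sum(shared$shared_n)
    report$shared_universe <- universe
  }

  # --- stage 6: promoter motif scanning (round trip through files)
  promoters <- extract_promoters(genome_path, annotation)
  hits <- scan_pwm(pwms, promoters, config$scan_threshold)
  mt <- gene_motif_table(hits, genes = names(promoters$seqs),
                         pwm_ids = names(pwms),
                         families = config$motif_families)
  enr <- motif_enrichment(intersect(common$gene, rownames(mt$presence)),
                          rownames(mt$presence), mt)
  report$n_motif_genes <- colSums(mt$presence[common$gene, , drop = FALSE])

  # --- stage 7: induction statistics
  groups <- assign_motif_groups(common$gene, mt, config$group_motifs)
  ref_model <- cluster_models[1]
  fin <- de[[ref_model]][[final_contrast[[ref_model]]]]
  lfc <- stats::setNames(fin$log2FC, fin$gene)[common$gene]
  comparison <- compare_groups(lfc, groups)
  ranks <- rank_analysis(lfc, groups)
  assignment <- stats::setNames(rep("no cluster", nrow(common)),
                                common$gene)
  ca <- clusters[[ref_model]]$assignment
  assignment[names(ca)] <- as.character(ca)
  motif_sets <- lapply(colnames(mt$presence), function(m)
    rownames(mt$presence)[mt$presence[, m] > 0])
  names(motif_sets) <- colnames(mt$presence)
  cme <- cluster_motif_enrichment(assignment, motif_sets)
  spacing <- motif_spacing(hits[hits$gene %in% common$gene, , drop = FALSE],
                           pwms$ETS1, pwms$RUNX1)
  ora_res <- NULL
  if (!is.null(gmt_path) && file.exists(gmt_path)) {
    sets <- read_gmt(gmt_path)
    rpkm_cols <- do.call(cbind, lapply(models, function(mdl)
      timepoint_means(norm[[mdl]], mdl, "rpkm")))
    ora_res <- lapply(rownames(clusters[[ref_model]]$prototypes),
                      function(cl) {
      fg <- names(ca)[as.character(ca) == cl]
      ora(intersect(fg, common$gene), common$gene, sets, rpkm = rpkm_cols,
          rpkm_floor = config$rpkm_floor, fdr_max = config$ora_fdr,
          log2fc = lfc)
    })
    names(ora_res) <- rownames(clusters[[ref_model]]$prototypes)
    report$n_ora_enriched <- sum(vapply(ora_res, function(x)
      sum(x$enriched), integer(1)))
  }
  report$group_sizes <- stats::setNames(comparison$groups$n,
                                        comparison$groups$group)
  report$group_medians <- stats::setNames(comparison$groups$median,
                                          comparison$groups$group)
  report$group_median_ranks <- stats::setNames(ranks$median_rank,
                                               ranks$group)
  report$mean_spacing <- spacing$mean_spacing

  structure(
    list(report = report, config = config, truth = truth, counts = counts,
         norm = norm, de = de, common = common, clusters = clusters,
         pairing = pairing, shared = shared, promoters = promoters,
         hits = hits, motif_table = mt, motif_enrichment = enr,
         groups = groups, comparison = comparison, ranks = ranks,
         cluster_motif = cme, spacing = spacing, ora = ora_res),
    class = "hsc_run"
  )
}

#' Write the pipeline's tables and run report to a directory
#'
#' All outputs are plain TSV/JSON written deterministically (no
#' timestamps), so identical runs produce byte-identical files.
#'
#' @param run an [run_pipeline()] result.
#' @param outdir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_pipeline_outputs <- function(run, outdir) {
  stopifnot(inherits(run, "hsc_run"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wt <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
  }
  wt(as.data.frame(run$common), "common_genes.tsv")
  for (mdl in names(run$de)) {
    fin <- run$de[[mdl]][[length(run$de[[mdl]])]]
    wt(as.data.frame(fin), sprintf("de_%s_final.tsv", mdl))
  }
  for (mdl in names(run$clusters)) {
    cs <- run$clusters[[mdl]]
    wt(data.frame(gene = names(cs$assignment), cluster = cs$assignment,
                  fit = cs$fit[names(cs$assignment)], row.names = NULL),
       sprintf("clusters_%s.tsv", mdl))
    wt(data.frame(cluster = rownames(cs$prototypes), cs$prototypes,
                  check.names = FALSE), sprintf("prototypes_%s.tsv", mdl))
  }
  if (!is.null(run$shared))
    wt(run$shared[, setdiff(names(run$shared), "genes")], "cluster_pairs.tsv")
  wt(run$hits, "motif_hits.tsv")
  wt(data.frame(gene = rownames(run$motif_table$presence),
                run$motif_table$presence, check.names = FALSE),
     "motif_presence.tsv")
  wt(run$motif_enrichment, "motif_enrichment.tsv")
  wt(run$comparison$groups, "motif_group_comparison.tsv")
  wt(run$comparison$pairs, "motif_group_pairs.tsv")
  wt(run$ranks, "motif_group_ranks.tsv")
  wt(run$cluster_motif, "cluster_motif_enrichment.tsv")
  rp <- file.path(outdir, "report.json")
  jsonlite::write_json(run$report, rp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths[["report.json"]] <- rp
  invisible(paths)
}
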