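test_that("generation is deterministic for a fixed seed", {
  cfg <- small_config(n_genes = 120, seed = 11)
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1$genes, t2$genes)
  expect_identical(t1$motifs, t2$motifs)
  expect_identical(as.character(t1$promoters), as.character(t2$promoters))
  c1 <- simulate_counts(t1); c2 <- simulate_counts(t2)
  expect_identical(c1$WD$counts, c2$WD$counts)
  # a different seed changes the realization
  t3 <- generate_truth(small_config(n_genes = 120, seed = 12))
  expect_false(identical(t1$motifs, t3$motifs))
})

test_that("planted cluster fractions follow the configured proportions", {
  cfg <- small_config(n_genes = 4000, seed = 2, frac_regulated = 0.5)
  tr <- generate_truth(cfg)
  tab <- table(tr$genes$planted_cluster)
  expect_equal(unname(tab[["null"]]) / 4000, 0.5, tolerance = 0.05)
  reg <- tr$genes$planted_cluster != "null"
  for (cl in names(cfg$cluster_proportions)) {
    frac <- sum(tr$genes$planted_cluster == cl) / sum(reg)
    expect_equal(frac, unname(cfg$cluster_proportions[[cl]]),
                 tolerance = 3 * sqrt(0.25 / sum(reg)) /
                   max(cfg$cluster_proportions[[cl]], 0.1))
  }
})

test_that("motif coupling extremes behave as configured", {
  # coupling 1: every induced-cluster promoter carries both motifs
  tr1 <- generate_truth(small_config(n_genes = 400, seed = 3,
                                     motif_coupling = 1))
  ind <- tr1$genes$gene_id[tr1$genes$planted_cluster == "cluster6"]
  for (m in c("ETS1", "RUNX1")) {
    with_m <- unique(tr1$motifs$gene[tr1$motifs$motif == m])
    expect_true(all(ind %in% with_m))
  }
  # coupling 0 with equal background: presence independent of cluster
  tr0 <- generate_truth(small_config(
    n_genes = 2000, seed = 4, motif_coupling = 0, p_single_induced = 0.12,
    p_background = c(ETS1 = 0.12, RUNX1 = 0.05, AP1 = 0.10),
    p_ap1_induced = 0.10, dual_shift = 0))
  has_ets <- tr0$genes$gene_id %in%
    tr0$motifs$gene[tr0$motifs$motif == "ETS1"]
  induced <- tr0$genes$planted_cluster == "cluster6"
  p <- chisq.test(table(has_ets, induced))$p.value
  expect_gt(p, 1e-3)
})

test_that("simulated counts follow the NB mean-variance relation", {
  # Poisson limit: variance ~ mean
  cfg0 <- synthetic_config(
    n_genes = 2500, seed = 5, dispersion = 0, frac_regulated = 0,
    baseline_log2_sd = 0, baseline_log2_mean = log2(100),
    lib_range = c(1e6, 1e6), models = list(WD = c(0, 12, 16, 24)),
    replicates = 3)
  cnt0 <- simulate_counts(generate_truth(cfg0))$WD
  x0 <- as.numeric(cnt0$counts)
  expect_gt(var(x0) / mean(x0), 0.9)
  expect_lt(var(x0) / mean(x0), 1.1)

  # phi = 0.5 at mu = 100: variance ~ mu + phi mu^2 = 5100 within 10%
  cfg5 <- synthetic_config(
    n_genes = 2500, seed = 6, dispersion = 0.5, frac_regulated = 0,
    baseline_log2_sd = 0, baseline_log2_mean = log2(100),
    lib_range = c(1e6, 1e6), models = list(WD = c(0, 12, 16, 24)),
    replicates = 3)
  cnt5 <- simulate_counts(generate_truth(cfg5))$WD
  x5 <- as.numeric(cnt5$counts)
  expect_equal(var(x5), 100 + 0.5 * 100^2, tolerance = 0.1)
})

test_that("a planted trajectory shifts the realized mean accordingly", {
  shapes <- matrix(c(0, 0, 0, 1), 1, dimnames = list("clusterX", NULL))
  profs <- list(shapes = shapes, amplitudes = c(clusterX = 2))
  cfg <- synthetic_config(
    n_genes = 3000, seed = 7, dispersion = 0.1, frac_regulated = 0.5,
    profiles = profs, cluster_proportions = c(clusterX = 1),
    induced_cluster = "clusterX", repressed_cluster = "clusterX",
    baseline_log2_sd = 0, baseline_log2_mean = 5, dual_shift = 0,
    lib_range = c(1e6, 1e6), models = list(WD = c(0, 12, 16, 24)))
  tr <- generate_truth(cfg)
  cnt <- simulate_counts(tr)$WD
  planted <- tr$genes$planted_cluster == "clusterX"
  final <- cnt$samples$time == 24
  ratio <- mean(cnt$counts[planted, final]) /
    mean(cnt$counts[planted, cnt$samples$time == 0])
  expect_equal(ratio, 4, tolerance = 0.1)  # log2FC (0,0,0,2) => 4x
  # null genes: realized log2FC centred at zero
  nulls <- !planted
  lfc <- log2(rowMeans(cnt$counts[nulls, final]) + 0.5) -
    log2(rowMeans(cnt$counts[nulls, cnt$samples$time == 0]) + 0.5)
  expect_lt(abs(mean(lfc)), 0.05)
})

test_that("written genome/annotation round-trips every planted motif", {
  cfg <- small_config(n_genes = 150, seed = 8)
  tr <- generate_truth(cfg)
  outdir <- withr::local_tempdir()
  paths <- write_genome_and_annotation(tr, outdir)

  # FASTA format contract: 60-column lines, unique record ids
  fa <- readLines(paths[["genome"]])
  ids <- sub("^>", "", fa[grepl("^>", fa)])
  expect_false(any(duplicated(ids)))
  seq_lines <- fa[!grepl("^>", fa)]
  expect_true(all(nchar(seq_lines) <= 60))
  expect_equal(sort(unique(nchar(seq_lines)))[length(unique(nchar(seq_lines)))], 60)

  ann <- read_annotation(paths[["annotation"]])
  prom <- extract_promoters(paths[["genome"]], ann)
  expect_identical(unname(as.character(prom$seqs[tr$genes$gene_id])),
                   unname(as.character(tr$promoters)))

  # scanner recovers every planted instance at its position and strand
  pwms <- read_pwm(paths[["pwms"]])
  hits <- scan_pwm(pwms, prom, threshold_frac = cfg$site_threshold)
  key_hit <- paste(hits$gene, hits$pwm, hits$start, hits$strand)
  key_truth <- paste(tr$motifs$gene, tr$motifs$motif, tr$motifs$pos,
                     tr$motifs$strand)
  expect_true(all(key_truth %in% key_hit))
})

test_that("config validation rejects impossible settings", {
  expect_error(synthetic_config(cluster_proportions = c(cluster1 = 0.5,
                                                        cluster6 = 0.4)),
               "sum to 1")
  expect_error(synthetic_config(dispersion = -0.1), "dispersion")
  expect_error(synthetic_config(promoter_len = 8), "widest PWM")
})
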