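test_that("PWM construction applies pseudocounts and log-odds correctly", {
  counts <- matrix(c(10, 0, 0, 0,
                     5, 5, 5, 5,
                     0, 10, 0, 0,
                     0, 0, 10, 0,
                     0, 0, 0, 10), 4, 5)
  pwm <- make_pwm(counts, "toy")
  expect_equal(unname(pwm$prob["A", 1]), 10.2 / 10.8, tolerance = 1e-12)
  expect_equal(unname(pwm$logodds["A", 1]), log2((10.2 / 10.8) / 0.25),
               tolerance = 1e-12)  # ~1.918 bits
  # an all-equal column has zero log-odds for every base
  expect_equal(unname(pwm$logodds[, 2]), rep(0, 4), tolerance = 1e-12)
  expect_true(all(abs(colSums(pwm$prob) - 1) < 1e-9))
  expect_error(make_pwm(counts[1:3, ], "bad"), "4 rows")
})

test_that("JASPAR write/read round-trip preserves matrices", {
  pwms <- default_pwms()
  f <- withr::local_tempfile(fileext = ".jaspar")
  write_pwm(pwms, f)
  back <- read_pwm(f)
  expect_identical(names(back), names(pwms))
  for (id in names(pwms)) {
    expect_equal(back[[id]]$counts, pwms[[id]]$counts, tolerance = 1e-9)
    expect_equal(back[[id]]$logodds, pwms[[id]]$logodds, tolerance = 1e-9)
  }
  writeLines(c(">X broken", "A [ 1 2 ]", "C [ 1 x ]", "G [ 1 2 ]",
               "T [ 1 2 ]"), f)
  expect_error(read_pwm(f), "non-numeric")
})

test_that("promoter extraction follows the strand-aware window convention", {
  # contig of 2000 bp with recognizable content
  set.seed(21)
  contig <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                  collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = contig))
  ann <- data.frame(
    gene_id = c("plus", "minus", "edge"),
    chrom = "chr1", strand = c("+", "-", "+"),
    tss_0based = c(1000, 1000, 100), length_bp = 500,
    planted_cluster = NA)
  expect_message(pr <- extract_promoters(genome, ann), "excluded")
  expect_identical(pr$excluded, "edge")  # window would start at -200
  # + strand: [700, 1050) as-is
  expect_identical(as.character(pr$seqs[["plus"]]),
                   substr(contig, 701, 1050))
  # - strand: reverse complement of [951, 1301)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(contig, 952, 1301))))
  expect_identical(as.character(pr$seqs[["minus"]]), rc)
  expect_equal(unname(Biostrings::width(pr$seqs)), c(350, 350))
  expect_error(extract_promoters(genome, transform(ann, chrom = "chrX")),
               "unknown contig")
})

test_that("scanning finds embedded consensus sites on both strands", {
  pwm <- default_pwms()$ETS1
  consensus <- "ACAGGAAGTG"
  set.seed(22)
  bg <- sample(c("A", "C", "G", "T"), 350, replace = TRUE)
  fwd <- bg; fwd[121:130] <- strsplit(consensus, "")[[1]]
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(consensus)))
  rev <- bg; rev[201:210] <- strsplit(rc, "")[[1]]
  seqs <- Biostrings::DNAStringSet(c(f = paste(fwd, collapse = ""),
                                     r = paste(rev, collapse = "")))
  hits <- scan_pwm(pwm, seqs)
  hf <- hits[hits$gene == "f" & hits$start == 120, ]
  expect_equal(nrow(hf), 1)
  expect_identical(hf$strand, "+")
  expect_equal(hf$score, pwm$max_score, tolerance = 1e-9)
  hr <- hits[hits$gene == "r" & hits$start == 200, ]
  expect_equal(nrow(hr), 1)
  expect_identical(hr$strand, "-")
  expect_equal(hr$score, pwm$max_score, tolerance = 1e-9)
})

test_that("hit sets equal brute-force window rescoring", {
  set.seed(23)
  pwms <- default_pwms()
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
               collapse = "")
    # spike in a couple of sites so hits exist
    site <- stellate:::sample_pwm_site(pwms$RUNX1)
    substr(s, 50, 49 + nchar(site)) <- site
    seqs <- Biostrings::DNAStringSet(c(g = s))
    for (pwm in pwms[c("ETS1", "RUNX1")]) {
      mine <- scan_pwm(pwm, seqs, 0.7)
      oracle <- oracle_scan(pwm, s, 0.7)
      key_m <- sort(paste(mine$start, mine$strand))
      key_o <- sort(paste(oracle$start, oracle$strand))
      expect_identical(key_m, key_o)
      expect_equal(sort(mine$score), sort(oracle$score), tolerance = 1e-9)
    }
  }
})

test_that("scanning the reverse complement mirrors hits with flipped strands", {
  set.seed(24)
  cfg <- small_config(n_genes = 60, seed = 24)
  tr <- generate_truth(cfg)
  pwm <- tr$pwms$ETS1
  hits <- scan_pwm(pwm, tr$promoters)
  rc <- Biostrings::reverseComplement(tr$promoters)
  names(rc) <- names(tr$promoters)
  hits_rc <- scan_pwm(pwm, rc)
  L <- 350
  mirrored <- data.frame(
    gene = hits$gene,
    start = L - pwm$width - hits$start,
    strand = ifelse(hits$strand == "+", "-", "+"))
  key1 <- sort(paste(mirrored$gene, mirrored$start, mirrored$strand))
  key2 <- sort(paste(hits_rc$gene, hits_rc$start, hits_rc$strand))
  expect_identical(key1, key2)
})

test_that("ZOOPS table binarizes, collapses families, and keeps zero rows", {
  hits <- data.frame(
    gene = c("g1", "g1", "g1", "g2", "g3"),
    pwm = c("ETS1", "ETS1", "ETS1", "ELK1", "RUNX1"),
    start = c(10, 50, 90, 5, 7), strand = "+", score = 10)
  tab <- gene_motif_table(hits, genes = c("g1", "g2", "g3", "g4"),
                          pwm_ids = c("ETS1", "ELK1", "RUNX1"),
                          families = list(ETS1_like = c("ETS1", "ELK1")))
  expect_equal(tab$count["g1", "ETS1"], 3L)
  expect_equal(tab$presence["g1", "ETS1"], 1L)
  expect_equal(tab$presence["g2", "ETS1_like"], 1L)  # OR semantics
  expect_equal(unname(tab$presence["g4", ]), rep(0L, 4))  # kept, all-zero
  expect_error(gene_motif_table(hits, c("g1"), pwm_ids = "ETS1",
                                families = list(f = "NOPE")),
               "no scanned members")
})

test_that("motif enrichment follows the ZOOPS hypergeometric definition", {
  genes <- sprintf("g%04d", 1:1000)
  pres <- matrix(0L, 1000, 1, dimnames = list(genes, "M"))
  pres[1:100, 1] <- 1L  # 100 background genes carry the motif
  tab <- structure(list(presence = pres), class = "hsc_motif_table")
  target <- c(genes[1:25], genes[101:125])  # 25 of 50 carry it
  res <- motif_enrichment(target, genes, tab)
  expect_equal(res$fold, 5)  # (25/50)/(100/1000)
  expect_equal(res$p, phyper(24, 100, 900, 50, lower.tail = FALSE),
               tolerance = 1e-12)
  res_all <- motif_enrichment(genes, genes, tab)
  expect_equal(res_all$fold, 1)
  expect_equal(res_all$p, 1)
  expect_error(motif_enrichment(c("nope"), genes, tab), "background")
})

test_that("motif spacing uses nearest midpoints per promoter", {
  pa <- default_pwms()$ETS1   # width 10, midpoint start + 5
  pb <- default_pwms()$RUNX1  # width 9, midpoint start + 4.5
  hits <- data.frame(
    gene = c("g1", "g1", "g2", "g2", "g2"),
    pwm = c("ETS1", "RUNX1", "ETS1", "ETS1", "RUNX1"),
    start = c(95, 172.5 - 4.5, 45, 195, 55.5 - 4.5),
    strand = "+", score = 1)
  sp <- motif_spacing(hits, pa, pb)
  # g1: midpoints 100 and 172.5 -> 72.5; g2: min(|50-55.5|, |200-55.5|)
  expect_equal(sort(sp$per_gene$spacing), sort(c(72.5, 5.5)))
  expect_equal(sp$mean_spacing, mean(c(72.5, 5.5)))
  none <- motif_spacing(hits[hits$pwm == "ETS1", ], pa, pb)
  expect_true(none$undefined)

  # planted fixed 30-bp midpoint spacing is recovered exactly
  set.seed(25)
  rows <- list()
  for (g in sprintf("g%02d", 1:40)) {
    a <- runif(1, 20, 250)
    rows[[g]] <- data.frame(gene = g, pwm = c("ETS1", "RUNX1"),
                            start = c(a - 5, a + 30 - 4.5), strand = "+",
                            score = 1)
  }
  sp30 <- motif_spacing(do.call(rbind, rows), pa, pb)
  expect_equal(sp30$mean_spacing, 30, tolerance = 1e-9)
})

test_that("hit-derived position frequency matrices recover the consensus", {
  cfg <- small_config(n_genes = 120, seed = 26)
  tr <- generate_truth(cfg)
  hits <- scan_pwm(tr$pwms$ETS1, tr$promoters)
  pfm <- hit_pfm(hits, tr$promoters, tr$pwms$ETS1)
  expect_equal(sum(pfm[, 1]), nrow(hits))
  consensus <- strsplit("ACAGGAAGT", "")[[1]]  # sharp positions 1..9
  top <- rownames(pfm)[apply(pfm[, 1:9], 2, which.max)]
  expect_identical(top, consensus)
})
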