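make_presence_table <- function(genes, ets, runx) {
  pres <- matrix(0L, length(genes), 2,
                 dimnames = list(genes, c("ETS1_like", "RUNX1")))
  pres[ets, "ETS1_like"] <- 1L
  pres[runx, "RUNX1"] <- 1L
  structure(list(presence = pres), class = "hsc_motif_table")
}

test_that("motif groups partition the gene set", {
  genes <- c("g1", "g2", "g3", "g4")
  tab <- make_presence_table(genes, ets = c("g1", "g3"), runx = c("g2", "g3"))
  grp <- assign_motif_groups(genes, tab)
  expect_identical(as.character(grp[["g1"]]), "ETS1_like_only")
  expect_identical(as.character(grp[["g2"]]), "RUNX1_only")
  expect_identical(as.character(grp[["g3"]]), "both")
  expect_identical(as.character(grp[["g4"]]), "none")
  expect_equal(sum(table(grp)), length(genes))
  expect_error(assign_motif_groups(c(genes, "g9"), tab), "missing")
})

test_that("group comparison medians, exact p-values and letters are coherent", {
  lfc <- setNames(c(1, 2, 3, 4), c("a1", "a2", "b1", "b2"))
  grp <- factor(setNames(c("A", "A", "B", "B"), names(lfc)))
  res <- compare_groups(lfc, grp)
  expect_equal(res$pairs$p, 1 / 3)  # {1,2} vs {3,4} exact two-sided
  expect_equal(res$groups$median, c(1.5, 3.5))

  # identical groups: p = 1, same letter
  lfc2 <- setNames(rep(c(1, 2, 3), 2), sprintf("g%d", 1:6))
  grp2 <- factor(setNames(rep(c("A", "B"), each = 3), names(lfc2)))
  res2 <- compare_groups(lfc2, grp2)
  expect_equal(res2$pairs$p, 1)
  expect_identical(res2$groups$letter[1], res2$groups$letter[2])

  # letter classes are exactly the non-significant components
  set.seed(31)
  lfc3 <- setNames(c(rnorm(20), rnorm(20, 5), rnorm(20, 5.2)),
                   sprintf("g%02d", 1:60))
  grp3 <- factor(setNames(rep(c("lo", "hi1", "hi2"), each = 20),
                          names(lfc3)))
  res3 <- compare_groups(lfc3, grp3)
  lt <- setNames(res3$groups$letter, res3$groups$group)
  for (i in seq_len(nrow(res3$pairs))) {
    same <- lt[[res3$pairs$group1[i]]] == lt[[res3$pairs$group2[i]]]
    if (res3$pairs$fdr[i] < 0.05) expect_false(same)
  }
  expect_error(compare_groups(lfc, factor(rep("A", 4))), "two non-empty")
})

test_that("rank analysis ranks descending with average ties", {
  lfc <- setNames(c(5, 3, 1), c("a", "b", "c"))
  grp <- factor(setNames(c("X", "X", "Y"), names(lfc)))
  ra <- rank_analysis(lfc, grp)
  expect_equal(ra$median_rank[ra$group == "X"], 1.5)
  expect_equal(ra$median_rank[ra$group == "Y"], 3)

  lfc2 <- setNames(c(5, 3, 3), c("a", "b", "c"))
  r <- rank(-lfc2, ties.method = "average")
  expect_equal(unname(r), c(1, 2.5, 2.5))

  # a group holding the top-k genes has median rank (k + 1) / 2
  k <- 7
  lfc3 <- setNames(seq(100, 1, length.out = 50), sprintf("g%02d", 1:50))
  grp3 <- factor(setNames(rep(c("top", "rest"), c(k, 43)), names(lfc3)))
  ra3 <- rank_analysis(lfc3, grp3)
  expect_equal(ra3$median_rank[ra3$group == "top"], (k + 1) / 2)
})

test_that("cluster x motif enrichment ratios, tails and additivity", {
  universe <- sprintf("g%03d", 1:800)
  assignment <- setNames(rep(c("1", "2", "no cluster"), c(50, 550, 200)),
                         universe)
  motif <- c(universe[1:25], universe[600:774])  # 25 in cluster 1, 200 total
  cme <- cluster_motif_enrichment(assignment, list(M = motif))
  row1 <- cme[cme$cluster == "1" & cme$motif == "M", ]
  expect_equal(row1$count, 25)
  expect_equal(row1$ratio, (25 / 50) / (200 / 800))  # = 2.0
  expect_equal(row1$p, phyper(24, 50, 750, 200, lower.tail = FALSE),
               tolerance = 1e-12)
  # counts over clusters (incl. "no cluster") add up to the motif total
  expect_equal(sum(cme$count), 200)
  # zero overlap: ratio 0, p = 1
  cme0 <- cluster_motif_enrichment(assignment,
                                   list(Z = universe[51:60]))
  z1 <- cme0[cme0$cluster == "1", ]
  expect_equal(z1$ratio, 0)
  expect_equal(z1$p, 1)
})

test_that("ORA applies the expression filter and exact hypergeometric tail", {
  genes <- sprintf("g%04d", 1:1000)
  sets <- list(PLANTED = genes[1:20], DECOY = genes[500:540])
  fg <- genes[1:50]
  res <- ora(fg, genes, sets)
  expect_lt(res$p[res$set == "PLANTED"], 1e-20)  # all 20 members in fg
  expect_equal(res$p[res$set == "PLANTED"],
               phyper(19, 20, 980, 50, lower.tail = FALSE),
               tolerance = 1e-25)

  # RPKM >= 10 at any time point: a gene at exactly 10.0 is retained
  rpkm <- matrix(1, 1000, 3, dimnames = list(genes, NULL))
  rpkm[1:49, 1] <- 50
  rpkm["g0050", 2] <- 10.0
  res2 <- ora(fg, genes, sets, rpkm = rpkm, rpkm_floor = 10)
  expect_equal(res2$foreground_n[1], 50)  # g0050 kept by the closed bound
  rpkm["g0050", 2] <- 9.999
  res3 <- ora(fg, genes, sets, rpkm = rpkm, rpkm_floor = 10)
  expect_equal(res3$foreground_n[1], 49)

  expect_warning(ora(fg, genes, sets, rpkm = rpkm * 0, rpkm_floor = 10),
                 "empty foreground")
  expect_error(ora(c("zz"), genes, sets), "contained")

  # median log2FC of the enriched set's members is reported
  lfc <- setNames(seq(0, 10, length.out = 1000), genes)
  res4 <- ora(fg, genes, sets, log2fc = lfc)
  expect_equal(res4$median_log2fc[res4$set == "PLANTED"],
               median(lfc[genes[1:20]]))
})

test_that("GMT parsing keeps set names, descriptions and members", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SET_A\tfirst set\tg1\tg2\tg3",
               "SET_B\tsecond set\tg2\tg4"), f)
  sets <- read_gmt(f)
  expect_identical(names(sets), c("SET_A", "SET_B"))
  expect_identical(sets$SET_A, c("g1", "g2", "g3"))
  expect_identical(attr(sets, "description")[2], "second set")
  writeLines("BAD\tonly-description", f)
  expect_error(read_gmt(f), "fewer than 3")
})

test_that("planted dual-motif coupling yields higher induction for 'both'", {
  set.seed(33)
  wins <- 0
  for (i in 1:10) {
    n_both <- 30; n_none <- 300
    genes <- sprintf("g%03d", seq_len(n_both + n_none))
    lfc <- setNames(c(rnorm(n_both, 4), rnorm(n_none, 2)), genes)
    tab <- make_presence_table(genes, ets = genes[1:n_both],
                               runx = genes[1:n_both])
    grp <- assign_motif_groups(genes, tab)
    res <- compare_groups(lfc, grp)
    ra <- rank_analysis(lfc, grp)
    ok <- res$groups$median[res$groups$group == "both"] >
      res$groups$median[res$groups$group == "none"] &&
      ra$median_rank[ra$group == "both"] <
        ra$median_rank[ra$group == "none"] &&
      res$pairs$fdr[1] < 0.05
    if (ok) wins <- wins + 1
  }
  expect_gte(wins, 9)
})
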