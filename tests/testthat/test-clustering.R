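test_that("vst_scale applies log2(x+1) then per-gene z-scoring", {
  m <- matrix(c(0, 1, 3, 7,
                5, 5, 5, 5), 2, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2"), NULL))
  sc <- vst_scale(m)
  expect_equal(unname(sc$profiles["g1", ]),
               c(-1.1619, -0.3873, 0.3873, 1.1619), tolerance = 1e-4)
  expect_identical(sc$constant, "g2")  # constant row flagged and excluded

  # mean/sd contract on random rows
  set.seed(1)
  r <- matrix(rexp(50 * 5), 50)
  rownames(r) <- sprintf("g%02d", 1:50)
  p <- vst_scale(r)$profiles
  expect_true(all(abs(rowMeans(p)) < 1e-9))
  expect_true(all(abs(apply(p, 1, sd) - 1) < 1e-9))
  expect_error(vst_scale(matrix(-1, dimnames = list("g", NULL))),
               "non-negative")
})

test_that("PAM separates identical-profile groups perfectly", {
  set.seed(2)
  base <- rbind(c(-1, 0, 1, 2), c(2, 1, 0, -1))
  prof <- base[rep(1:2, each = 10), ] +
    matrix(rnorm(80, sd = 1e-6), 20)  # distinct rows, identical shapes
  rownames(prof) <- sprintf("g%02d", 1:20)
  prof <- t(scale(t(prof)))
  cs <- pam_cluster(prof, 2)
  expect_equal(length(unique(cs$assignment[1:10])), 1)
  expect_equal(length(unique(cs$assignment[11:20])), 1)
  expect_lt(pam_cost(cs), 1e-9)
  # a profile and its negation always split at k = 2 (distance 2 maximal)
  expect_false(cs$assignment[1] == cs$assignment[11])
  expect_error(pam_cluster(prof, 1), "k must be")
})

test_that("PAM attains the exhaustive-search optimum on small instances", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(6:8, 1)
    prof <- matrix(rnorm(n * 5), n)
    rownames(prof) <- sprintf("g%d", seq_len(n))
    cs <- pam_cluster(prof, 2)
    expect_equal(pam_cost(cs), oracle_pam_cost(prof, 2), tolerance = 1e-9)
  }
})

test_that("silhouette-based k selection finds planted structure", {
  set.seed(4)
  u <- (seq_len(6) - 0.5) / 6  # midpoint grid: Fourier shapes uncorrelated
  protos <- rbind(sin(2 * pi * u), cos(2 * pi * u), sin(4 * pi * u))
  expect_lt(max(abs(cor(t(protos))[upper.tri(diag(3))])), 0.2)
  made <- make_planted_profiles(protos, 90, noise_sd = 0.2)
  k <- choose_k(made$profiles, 2:6)
  expect_equal(as.integer(k), 3)

  # two antipodal shapes
  made2 <- make_planted_profiles(rbind(c(-1, 0, 1), c(1, 0, -1)), 40, 0.1)
  expect_equal(as.integer(choose_k(made2$profiles, 2:5)), 2)

  # silhouette of perfect separation is 1
  cs <- pam_cluster(made2$profiles, 2)
  expect_gt(cs$avg_silhouette, 0.95)

  # degenerate input: identical profiles
  same <- matrix(rep(c(-1, 0, 1), each = 10), 10)
  rownames(same) <- sprintf("g%02d", 1:10)
  expect_warning(kd <- choose_k(same, 2:4), "identical")
  expect_equal(as.integer(kd), 2)
})

test_that("fit filter drops the configured fraction and small clusters", {
  set.seed(5)
  protos <- rbind(c(-2, -1, 0, 1, 2), c(2, 1, 0, -1, -2))
  made <- make_planted_profiles(protos, 100, noise_sd = 0.3)
  cs <- pam_cluster(made$profiles, 2)
  f <- fit_filter(cs, drop_frac = 0.10, min_cluster_size = 2)
  expect_equal(length(f$discarded), 10)   # floor(100 * 0.10)
  expect_equal(length(f$assignment), 90)
  f0 <- fit_filter(cs, drop_frac = 0, min_cluster_size = 2)
  expect_equal(length(f0$discarded), 0)
  expect_error(fit_filter(cs, drop_frac = 1), "drop_frac")

  # a planted shuffled-profile outlier lands in the discarded set
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    made <- make_planted_profiles(protos, 60, noise_sd = 0.25)
    prof <- made$profiles
    prof["g0001", ] <- sample(prof["g0001", ])  # destroy the shape
    prof <- t(scale(t(prof)))
    ff <- fit_filter(pam_cluster(prof, 2), drop_frac = 0.10,
                     min_cluster_size = 2)
    if ("g0001" %in% ff$discarded) hits <- hits + 1
  }
  expect_gte(hits, 9)

  # an undersized smallest cluster is removed post hoc
  small <- rbind(matrix(rep(c(-1, 0, 1, 2), each = 30), 30),
                 matrix(rep(c(2, 1, 0, -1), each = 25), 25),
                 matrix(rep(c(1, -2, 1, 0), each = 4), 4))
  small <- small + matrix(rnorm(length(small), sd = 0.05), nrow(small))
  rownames(small) <- sprintf("g%02d", seq_len(nrow(small)))
  small <- t(scale(t(small)))
  cs3 <- pam_cluster(small, 3)
  f3 <- fit_filter(cs3, drop_frac = 0, min_cluster_size = 20)
  expect_equal(length(f3$removed_clusters), 1)
  expect_equal(f3$k, 2)
})

test_that("prototypes are member means and fits behave", {
  prof <- matrix(rep(c(-1, 0, 1), each = 6), 6)
  rownames(prof) <- sprintf("g%d", 1:6)
  prof2 <- rbind(prof, t(replicate(6, c(1, 0, -1))))
  rownames(prof2) <- sprintf("g%02d", 1:12)
  cs <- pam_cluster(prof2, 2)
  pr <- cluster_prototypes(cs)
  expect_equal(pr$avg_fit, 1, tolerance = 1e-12)
  own <- cs$prototypes[as.character(cs$assignment["g01"]), ]
  expect_equal(unname(own), unname(prof2["g01", ]))

  # average fit never decreases after fit filtering
  set.seed(6)
  protos <- rbind(c(-2, -1, 0, 1, 2), c(0, 2, 0, -2, 0))
  made <- make_planted_profiles(protos, 80, noise_sd = 0.4)
  cs2 <- pam_cluster(made$profiles, 2)
  before <- cluster_prototypes(cs2)$avg_fit
  after <- cluster_prototypes(fit_filter(cs2, 0.10, 2))$avg_fit
  expect_gte(after, before)
})

test_that("planted six-shape structure is recovered (ARI) after filtering", {
  set.seed(7)
  u <- (seq_len(9) - 0.5) / 9
  protos <- rbind(sin(2 * pi * u), cos(2 * pi * u), sin(4 * pi * u),
                  cos(4 * pi * u), sin(6 * pi * u), cos(6 * pi * u))
  expect_lt(max(abs(cor(t(protos))[upper.tri(diag(6))])), 0.3)
  made <- make_planted_profiles(protos, 300, noise_sd = 0.25)
  cs <- fit_filter(pam_cluster(made$profiles, 6), 0.10, 2)
  truth <- made$labels[match(names(cs$assignment), rownames(made$profiles))]
  expect_gte(ari(cs$assignment, truth), 0.9)
})
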