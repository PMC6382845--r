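# Independent brute-force oracles used to check the package's
# implementations. Each oracle takes a different computational route from
# the function it validates.

# Conditional NB exact test by direct enumeration of the joint NB (or
# Poisson) probabilities at an arbitrary mean mu, normalized over all
# splits of the observed total. Independent of the closed-form conditional
# distribution used by nb_exact_test().
oracle_nb_exact <- function(ya, yb, phi, mu = 7.3) {
  na <- length(ya); nb <- length(yb)
  sa <- sum(ya); t <- sa + sum(yb)
  if (t == 0) return(1)
  a <- 0:t
  joint <- if (phi == 0) {
    dpois(a, na * mu) * dpois(t - a, nb * mu)
  } else {
    dnbinom(a, size = na / phi, mu = na * mu) *
      dnbinom(t - a, size = nb / phi, mu = nb * mu)
  }
  cond <- joint / sum(joint)
  min(1, sum(cond[cond <= cond[sa + 1] * (1 + 1e-10)]))
}

# Exhaustive k-medoids: minimal total 1 - r cost over all medoid subsets.
oracle_pam_cost <- function(profiles, k) {
  d <- 1 - cor(t(profiles))
  n <- nrow(profiles)
  best <- Inf
  for (med in utils::combn(n, k, simplify = FALSE)) {
    cost <- sum(apply(d[, med, drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

pam_cost <- function(cs) {
  d <- 1 - cor(t(cs$profiles))
  med_idx <- match(cs$medoids, rownames(cs$profiles))
  sum(apply(d[, med_idx, drop = FALSE], 1, min))
}

# Exact two-sided Wilcoxon rank-sum by enumeration of all group
# assignments (deviation-from-mean definition, as the implementation).
oracle_rank_sum <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y), ties.method = "average")
  w_obs <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  ws <- utils::combn(n, nx, function(idx) sum(r[idx]))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# Exact two-sided signed-rank by full 2^m sign-flip enumeration.
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(1)
  r <- rank(abs(d), ties.method = "average")
  w_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  ws <- vapply(0:(2^m - 1), function(mask) {
    sum(r[bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) > 0])
  }, numeric(1))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# Upper-tail hypergeometric by direct combinatorial summation.
oracle_hyper_upper <- function(n_a, n_b, overlap, universe) {
  ks <- overlap:min(n_a, n_b)
  sum(choose(n_a, ks) * choose(universe - n_a, n_b - ks)) /
    choose(universe, n_b)
}

# Naive PWM scan: rescore every window on both strands character by
# character.
oracle_scan <- function(pwm, seq_chr, threshold_frac = 0.80) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  thr <- threshold_frac * pwm$max_score
  L <- nchar(seq_chr)
  w <- pwm$width
  hits <- list()
  chars <- strsplit(seq_chr, "")[[1]]
  for (s0 in 0:(L - w)) {
    win <- chars[(s0 + 1):(s0 + w)]
    if (any(!win %in% names(comp))) next
    fw <- sum(vapply(seq_len(w), function(j) pwm$logodds[win[j], j],
                     numeric(1)))
    rc <- rev(unname(comp[win]))
    rv <- sum(vapply(seq_len(w), function(j) pwm$logodds[rc[j], j],
                     numeric(1)))
    if (fw >= thr - 1e-9)
      hits[[length(hits) + 1]] <- data.frame(start = s0, strand = "+",
                                             score = fw)
    if (rv >= thr - 1e-9)
      hits[[length(hits) + 1]] <- data.frame(start = s0, strand = "-",
                                             score = rv)
  }
  if (!length(hits)) return(data.frame(start = integer(),
                                       strand = character(),
                                       score = numeric()))
  do.call(rbind, hits)
}

# Adjusted Rand Index between two labelings.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Noisy profiles around planted prototype shapes, z-scored per gene:
# the input space of the clustering module.
make_planted_profiles <- function(prototypes, n_genes, noise_sd) {
  k <- nrow(prototypes)
  labels <- rep(seq_len(k), length.out = n_genes)
  raw <- prototypes[labels, , drop = FALSE] +
    matrix(rnorm(n_genes * ncol(prototypes), sd = noise_sd), n_genes)
  prof <- t(scale(t(raw)))
  rownames(prof) <- sprintf("g%04d", seq_len(n_genes))
  list(profiles = prof, labels = labels)
}
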