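# Cross-model cluster pairing: one-to-one assignment of clusters from two
# models maximizing total prototype Pearson correlation, shared-gene
# extraction, and hypergeometric overlap significance.

# Linear interpolation of a prototype onto an ordinal grid of a different
# length (used when the two models have different numbers of time points).
interp_profile <- function(p, len) {
  if (length(p) == len) return(p)
  stats::approx(seq(0, 1, length.out = length(p)), p,
                xout = seq(0, 1, length.out = len))$y
}

# Exact assignment maximizing total score by bitmask dynamic programming
# over the columns; rows beyond ncol are left unassigned upstream.
assign_max_total <- function(score) {
  n <- nrow(score); m <- ncol(score)
  stopifnot(n <= m)
  nmask <- bitwShiftL(1L, m)
  best <- matrix(-Inf, n + 1, nmask)
  best[1, 1] <- 0
  pick <- matrix(NA_integer_, n + 1, nmask)
  for (i in seq_len(n)) {
    for (mask in which(is.finite(best[i, ])) - 1L) {
      for (j in seq_len(m)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(mask, bit) == 0L) {
          nm <- bitwOr(mask, bit)
          val <- best[i, mask + 1L] + score[i, j]
          if (val > best[i + 1, nm + 1L]) {
            best[i + 1, nm + 1L] <- val
            pick[i + 1, nm + 1L] <- j
          }
        }
      }
    }
  }
  final <- which.max(best[n + 1, ])
  mask <- final - 1L
  res <- integer(n)
  for (i in seq(n, 1)) {
    j <- pick[i + 1, mask + 1L]
    res[i] <- j
    mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, j - 1L)))
  }
  res
}

#' Pair clusters across two models by prototype correlation
#'
#' Finds the one-to-one assignment between cluster prototypes of two models
#' that maximizes the total Pearson correlation (exact optimal assignment,
#' not greedy). When the models have different numbers of time points the
#' shorter prototype is linearly interpolated onto the longer ordinal grid.
#' With unequal cluster counts, min(kA, kB) pairs are formed and the rest
#' left unpaired with a warning.
#'
#' @param protos_a,protos_b cluster x timepoint prototype matrices (rownames
#'   are cluster ids), e.g. `$prototypes` of an `hsc_clusters`.
#' @return data.frame of class `hsc_pairing` with columns `a`, `b`, `r`,
#'   `low_confidence` (best-achievable r < 0); unpaired cluster ids in
#'   attribute `unpaired`.
#' @export
pair_clusters <- function(protos_a, protos_b) {
  protos_a <- as.matrix(protos_a); protos_b <- as.matrix(protos_b)
  len <- max(ncol(protos_a), ncol(protos_b))
  pa <- t(apply(protos_a, 1, interp_profile, len = len))
  pb <- t(apply(protos_b, 1, interp_profile, len = len))
  r_mat <- stats::cor(t(pa), t(pb))
  swap <- nrow(pa) > nrow(pb)
  score <- if (swap) t(r_mat) else r_mat
  idx <- assign_max_total(score)
  if (swap) {
    a_id <- rownames(protos_a)[idx]
    b_id <- rownames(protos_b)
    r <- score[cbind(seq_along(idx), idx)]
  } else {
    a_id <- rownames(protos_a)
    b_id <- rownames(protos_b)[idx]
    r <- score[cbind(seq_along(idx), idx)]
  }
  out <- data.frame(a = a_id, b = b_id, r = r,
                    low_confidence = r < 0, row.names = NULL)
  unpaired <- c(setdiff(rownames(protos_a), out$a),
                setdiff(rownames(protos_b), out$b))
  if (length(unpaired))
    warnf("unequal cluster counts; unpaired: %s",
          paste(unpaired, collapse = ", "))
  attr(out, "unpaired") <- unpaired
  attr(out, "r_matrix") <- r_mat
  class(out) <- c("hsc_pairing", "data.frame")
  out
}

#' Shared genes of paired clusters
#'
#' @param pairing a [pair_clusters()] result.
#' @param members_a,members_b named cluster assignment vectors (gene ->
#'   cluster id) for models A and B.
#' @return data.frame with per-pair `shared_n`, `percent_of_a` (share of
#'   the A-side parent cluster), and the gene sets as a list-column
#'   `genes`.
#' @export
shared_genes <- function(pairing, members_a, members_b) {
  stopifnot(inherits(pairing, "hsc_pairing"))
  rows <- lapply(seq_len(nrow(pairing)), function(i) {
    ga <- names(members_a)[as.character(members_a) == pairing$a[i]]
    gb <- names(members_b)[as.character(members_b) == pairing$b[i]]
    shared <- sort(intersect(ga, gb))
    data.frame(a = pairing$a[i], b = pairing$b[i], r = pairing$r[i],
               size_a = length(ga), size_b = length(gb),
               shared_n = length(shared),
               percent_of_a = if (length(ga)) 100 * length(shared) /
                 length(ga) else 0)
  })
  out <- do.call(rbind, rows)
  out$genes <- lapply(seq_len(nrow(pairing)), function(i) {
    ga <- names(members_a)[as.character(members_a) == pairing$a[i]]
    gb <- names(members_b)[as.character(members_b) == pairing$b[i]]
    sort(intersect(ga, gb))
  })
  out
}

#' Hypergeometric significance of a cluster-pair overlap
#'
#' Upper-tail probability P(X >= overlap) with X ~
#' Hypergeometric(universe_n, n_a, n_b): the chance of drawing at least the
#' observed overlap when n_b genes are drawn from a universe containing
#' n_a marked genes.
#'
#' @param n_a,n_b sizes of the two gene sets.
#' @param overlap observed intersection size.
#' @param universe_n size of the gene universe both sets are drawn from.
#' @return upper-tail p-value in (0, 1].
#' @export
overlap_significance <- function(n_a, n_b, overlap, universe_n) {
  if (n_a > universe_n || n_b > universe_n)
    stopf("set sizes exceed the universe")
  if (overlap > min(n_a, n_b)) stopf("overlap exceeds the smaller set")
  stats::phyper(overlap - 1, n_a, universe_n - n_a, n_b, lower.tail = FALSE)
}
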