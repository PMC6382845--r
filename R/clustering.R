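# Time-course clustering of common genes: variance-stabilized, scaled
# profiles partitioned by PAM (k-medoids) under Pearson correlation
# distance, with silhouette-based selection of k, a global fit filter, and
# post-hoc removal of an undersized cluster.

#' Variance-stabilize and scale average expression profiles
#'
#' Applies log2(x + 1) to per-time-point average expression, then z-scores
#' each gene across time points using the sample standard deviation
#' (divide by n - 1, the convention of [stats::sd()]; a row (0, 1, 3, 7)
#' scales to (-1.1619, -0.3873, 0.3873, 1.1619)). Rows constant after the
#' transform cannot be scaled; they are excluded from clustering and
#' reported.
#'
#' @param avg gene x timepoint matrix of non-negative averages (e.g. from
#'   [timepoint_means()]).
#' @return object of class `hsc_profiles`: list with `profiles` (scaled
#'   matrix over non-constant genes) and `constant` (excluded gene ids).
#' @export
vst_scale <- function(avg) {
  avg <- as.matrix(avg)
  if (any(avg < 0)) stopf("averages must be non-negative")
  x <- log2(avg + 1)
  n <- ncol(x)
  m <- rowMeans(x)
  s <- sqrt(rowSums((x - m)^2) / (n - 1))
  const <- s < 1e-12
  prof <- (x[!const, , drop = FALSE] - m[!const]) / s[!const]
  structure(list(profiles = prof, constant = rownames(x)[const]),
            class = "hsc_profiles")
}

cor_dist <- function(profiles) {
  stats::as.dist(1 - stats::cor(t(profiles)))
}

profile_matrix <- function(x) {
  if (inherits(x, "hsc_profiles")) x$profiles else as.matrix(x)
}

# prototype = arithmetic mean of member profiles; fit = Pearson r of each
# gene to its own prototype (NA when the prototype is essentially constant).
compute_prototypes <- function(profiles, assignment) {
  cl <- sort(unique(assignment))
  proto <- t(vapply(cl, function(k) {
    colMeans(profiles[assignment == k, , drop = FALSE])
  }, numeric(ncol(profiles))))
  rownames(proto) <- as.character(cl)
  fit <- rep(NA_real_, nrow(profiles))
  names(fit) <- rownames(profiles)
  for (k in cl) {
    idx <- which(assignment == k)
    pk <- proto[as.character(k), ]
    if (stats::sd(pk) < 1e-12) next  # degenerate prototype, fits undefined
    fit[idx] <- as.numeric(stats::cor(t(profiles[idx, , drop = FALSE]), pk))
  }
  list(prototypes = proto, fit = fit)
}

# Exhaustive k-medoids: scan every medoid subset (used when the search
# space is small enough that the global optimum is cheap; the swap
# heuristic can stall in local optima there).
exact_medoids <- function(dm, k) {
  combos <- utils::combn(nrow(dm), k, simplify = FALSE)
  costs <- vapply(combos, function(med) {
    sum(do.call(pmin, asplit(dm[, med, drop = FALSE], 2)))
  }, numeric(1))
  combos[[which.min(costs)]]
}

#' k-medoids clustering of scaled profiles under correlation distance
#'
#' Partitions genes into k clusters minimizing the total distance
#' d = 1 - r to the medoids, where r is the Pearson correlation between
#' scaled time-course profiles. Small instances (up to 3000 candidate
#' medoid sets) are solved exactly by exhaustive medoid enumeration;
#' larger ones by PAM's deterministic BUILD + swap phases
#' ([cluster::pam()]). Both routes are deterministic.
#'
#' @param x `hsc_profiles` object or scaled gene x timepoint matrix.
#' @param k number of clusters (2 <= k <= n genes).
#' @return object of class `hsc_clusters`: list with `k`, `assignment`
#'   (named integer), `medoids` (gene ids), `prototypes` (mean profile per
#'   cluster), `fit` (per-gene Pearson r to own prototype), `profiles`,
#'   `avg_silhouette`, `discarded`, `removed_clusters`.
#' @export
pam_cluster <- function(x, k) {
  profiles <- profile_matrix(x)
  n <- nrow(profiles)
  if (k < 2 || k > n) stopf("k must be in [2, %d]", n)
  d <- cor_dist(profiles)
  dm <- as.matrix(d)
  if (choose(n, k) <= 3000) {
    med_idx <- exact_medoids(dm, k)
    assignment <- apply(dm[, med_idx, drop = FALSE], 1, which.min)
  } else {
    fit <- cluster::pam(d, k = k, diss = TRUE)
    med_idx <- fit$id.med
    assignment <- fit$clustering
  }
  names(assignment) <- rownames(profiles)
  sil <- cluster::silhouette(assignment, dist = d)
  pr <- compute_prototypes(profiles, assignment)
  structure(
    list(k = k, assignment = assignment,
         medoids = rownames(profiles)[med_idx],
         prototypes = pr$prototypes, fit = pr$fit, profiles = profiles,
         avg_silhouette = mean(sil[, "sil_width"]),
         discarded = character(0), removed_clusters = integer(0)),
    class = "hsc_clusters"
  )
}

#' @export
print.hsc_clusters <- function(x, ...) {
  cat(sprintf("hsc_clusters: k = %d, %d genes (%d discarded)\n",
              x$k, length(x$assignment), length(x$discarded)))
  print(table(x$assignment))
  invisible(x)
}

#' Choose the number of clusters by average silhouette width
#'
#' Runs PAM over a range of k and returns the k maximizing the average
#' silhouette width under correlation distance; ties resolve to the
#' smallest k. Degenerate inputs (all profiles essentially identical)
#' return the smallest candidate k with a warning.
#'
#' @param x `hsc_profiles` object or scaled profile matrix.
#' @param k_range candidate cluster counts (default 2:12).
#' @return the selected k; the silhouette profile is attached as attribute
#'   `silhouette`.
#' @export
choose_k <- function(x, k_range = 2:12) {
  profiles <- profile_matrix(x)
  n <- nrow(profiles)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stopf("k_range must lie within [2, n - 1]")
  d <- cor_dist(profiles)
  if (max(d) < 1e-12) {
    warnf("all profiles are identical; returning smallest candidate k")
    return(min(k_range))
  }
  sil <- vapply(k_range, function(k) {
    pam_cluster(profiles, k)$avg_silhouette
  }, numeric(1))
  best <- k_range[which.max(sil)]  # which.max takes the first (smallest) tie
  attr(best, "silhouette") <- stats::setNames(sil, k_range)
  best
}

#' Filter poorly fitting genes and undersized clusters
#'
#' Drops the globally lowest `drop_frac` fraction of genes by fit (Pearson
#' r to own-cluster prototype; floor(n * drop_frac) genes, ties broken by
#' gene id), then removes the single smallest remaining cluster if its size
#' falls below `min_cluster_size`. Prototypes and fits are recomputed on
#' the retained genes.
#'
#' @param cs an `hsc_clusters` object.
#' @param drop_frac fraction of genes to discard by fit, in `[0, 1)`
#'   (default 0.10).
#' @param min_cluster_size post-hoc size threshold: the smallest cluster is
#'   removed only if smaller than this (default 20).
#' @return filtered `hsc_clusters` with `discarded` and `removed_clusters`
#'   populated.
#' @export
fit_filter <- function(cs, drop_frac = 0.10, min_cluster_size = 20) {
  stopifnot(inherits(cs, "hsc_clusters"))
  if (drop_frac < 0 || drop_frac >= 1) stopf("drop_frac must be in [0, 1)")
  genes <- names(cs$assignment)
  n <- length(genes)
  ndrop <- floor(n * drop_frac)
  fit <- cs$fit[genes]
  fit[is.na(fit)] <- -Inf  # undefined fits are the worst fits
  ord <- order(fit, genes)
  dropped <- genes[ord[seq_len(ndrop)]]
  keep <- setdiff(genes, dropped)

  assignment <- cs$assignment[keep]
  removed <- integer(0)
  sizes <- table(assignment)
  if (length(sizes) > 1) {
    smallest <- names(sizes)[which.min(sizes)]
    if (sizes[[smallest]] < min_cluster_size) {
      removed <- as.integer(smallest)
      dropped <- c(dropped, names(assignment)[assignment == removed])
      assignment <- assignment[assignment != removed]
    }
  }
  profiles <- cs$profiles[names(assignment), , drop = FALSE]
  pr <- compute_prototypes(profiles, assignment)
  structure(
    list(k = length(unique(assignment)), assignment = assignment,
         medoids = intersect(cs$medoids, names(assignment)),
         prototypes = pr$prototypes, fit = pr$fit, profiles = profiles,
         avg_silhouette = cs$avg_silhouette,
         discarded = sort(dropped), removed_clusters = removed),
    class = "hsc_clusters"
  )
}

#' Cluster prototypes and fit summary
#'
#' @param cs an `hsc_clusters` object.
#' @return list with `prototypes` (cluster x timepoint matrix of mean
#'   aggregate profiles), `avg_fit_per_cluster`, and `avg_fit` (mean
#'   member-to-prototype Pearson r overall, NA fits excluded).
#' @export
cluster_prototypes <- function(cs) {
  stopifnot(inherits(cs, "hsc_clusters"))
  cl <- rownames(cs$prototypes)
  per <- vapply(cl, function(k) {
    mean(cs$fit[names(cs$assignment)[cs$assignment == as.integer(k)]],
         na.rm = TRUE)
  }, numeric(1))
  list(prototypes = cs$prototypes, avg_fit_per_cluster = per,
       avg_fit = mean(cs$fit, na.rm = TRUE))
}
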