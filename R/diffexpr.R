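# Differential expression by the conditional negative-binomial exact test.
#
# The test conditions on each gene's total count across the two groups
# (after library sizes are equalized by pseudo-count scaling) and sums the
# probabilities of all splits no more likely than the observed one — the
# "small probabilities" flavour of the NB exact test for overdispersed
# counts. A single common dispersion per experiment is used; the conditional
# split distribution is negative hypergeometric with shape n_group/phi and
# reduces to a binomial split in the Poisson limit (phi = 0).

#' Equalize library sizes by pseudo-count scaling
#'
#' Scales every sample's counts to the geometric-mean library size and
#' rounds to the nearest integer — the standard precondition of the
#' conditional NB exact test.
#'
#' @param counts gene x sample matrix.
#' @param libsize per-sample library sizes.
#' @return matrix of equalized integer counts; the common library size is
#'   attached as attribute `common_libsize`.
#' @export
equalize_libsizes <- function(counts, libsize) {
  if (any(libsize <= 0)) stopf("library sizes must be positive")
  common <- exp(mean(log(libsize)))
  out <- round(sweep(counts, 2, common / libsize, "*"))
  attr(out, "common_libsize") <- common
  out
}

#' Method-of-moments common dispersion estimate
#'
#' Pools the NB moment relation var = mu + phi * mu^2 across all genes and
#' all replicated groups (on library-size-equalized counts):
#' phi = sum(var - mean) / sum(mean^2), floored at zero.
#'
#' @param cm an `hsc_counts` object.
#' @param groups factor of group membership per sample; defaults to
#'   model:time interaction.
#' @return non-negative dispersion estimate.
#' @export
estimate_common_dispersion <- function(cm, groups = NULL) {
  stopifnot(inherits(cm, "hsc_counts"))
  if (is.null(groups)) {
    groups <- interaction(cm$samples$model, cm$samples$time, drop = TRUE)
  }
  groups <- as.factor(groups)
  eq <- equalize_libsizes(cm$counts, cm$libsize)
  num <- 0; den <- 0; replicated <- FALSE
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    replicated <- TRUE
    sub <- eq[, idx, drop = FALSE]
    m <- rowMeans(sub)
    v <- row_vars(sub)
    keep <- m > 0
    num <- num + sum(v[keep] - m[keep])
    den <- den + sum(m[keep]^2)
  }
  if (!replicated)
    stopf("no group has >= 2 replicates; supply a dispersion explicitly")
  max(0, num / den)
}

# log conditional probability of splitting total t as (a, t - a) between
# groups of ra and rb NB units (r = n/phi); negative hypergeometric.
cond_log_pmf <- function(a, t, ra, rb) {
  lchoose(a + ra - 1, a) + lchoose(t - a + rb - 1, t - a) -
    lchoose(t + ra + rb - 1, t)
}

#' Conditional NB exact test for one two-group comparison
#'
#' For each gene, conditions on the total count across both groups and sums
#' the conditional probabilities of all splits whose probability does not
#' exceed the observed split's (two-sided). Counts must already be on a
#' common library size (see [equalize_libsizes()]).
#'
#' @param counts_a,counts_b gene x replicate matrices of equalized counts.
#' @param phi common NB dispersion (>= 0; 0 gives the Poisson/binomial
#'   limit).
#' @return numeric vector of two-sided p-values, one per gene.
#' @export
nb_exact_test <- function(counts_a, counts_b, phi) {
  counts_a <- as.matrix(counts_a); counts_b <- as.matrix(counts_b)
  if (nrow(counts_a) != nrow(counts_b)) stopf("gene sets differ")
  if (any(counts_a < 0) || any(counts_b < 0)) stopf("negative counts")
  if (phi < 0) stopf("dispersion must be >= 0")
  na <- ncol(counts_a); nb <- ncol(counts_b)
  sa <- rowSums(counts_a); sb <- rowSums(counts_b)
  tt <- sa + sb
  p <- rep(1, nrow(counts_a))
  nz <- which(tt > 0)
  for (i in nz) {
    t_i <- tt[i]
    a <- 0:t_i
    if (phi == 0) {
      lp <- stats::dbinom(a, t_i, na / (na + nb), log = TRUE)
    } else {
      lp <- cond_log_pmf(a, t_i, na / phi, nb / phi)
    }
    obs <- lp[sa[i] + 1]
    p[i] <- min(1, sum(exp(lp[lp <= obs + 1e-12])))
  }
  names(p) <- rownames(counts_a)
  p
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Wrapper around [stats::p.adjust()] that validates the input range and
#' excludes missing values from the number of tests.
#'
#' @param p vector of p-values in `[0, 1]` (NA/NaN propagated).
#' @return BH-adjusted values, clipped to 1.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stopf("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  names(out) <- names(p)
  out
}

#' Differential expression table for one contrast within one model
#'
#' Computes the NB exact test for `time_alt` vs `time_ref` within `model`.
#' log2 fold changes come from prior-count-stabilized group mean CPM. The
#' expression floor is applied on the mean log2CPM across *all* samples of
#' the model (one per-experiment threshold); genes at or below the floor
#' get an NA FDR and do not count towards the number of tests.
#'
#' @param cm an `hsc_counts` object (may contain several models).
#' @param model model label.
#' @param time_ref,time_alt reference (earlier) and alternative (later) time
#'   points; log2FC is alt minus ref.
#' @param phi common dispersion; NULL estimates it from this model's samples.
#' @param prior_count CPM prior for log2 values (default 0.5).
#' @param floor_log2cpm expression floor on mean log2CPM (default 2).
#' @return data.frame of class `hsc_de` with columns gene, log2FC, log2CPM,
#'   p, fdr; the contrast and dispersion are attached as attributes.
#' @export
de_table <- function(cm, model, time_ref, time_alt, phi = NULL,
                     prior_count = 0.5, floor_log2cpm = 2) {
  stopifnot(inherits(cm, "hsc_counts"))
  sel <- cm$samples$model == model
  if (!any(sel)) stopf("no samples for model '%s'", model)
  cmm <- subset_samples(cm, sel)
  ia <- cmm$samples$time == time_ref
  ib <- cmm$samples$time == time_alt
  if (!any(ia)) stopf("missing group: model %s time %s", model, time_ref)
  if (!any(ib)) stopf("missing group: model %s time %s", model, time_alt)
  if (is.null(phi)) phi <- estimate_common_dispersion(cmm)

  norm <- normalize_counts(cmm, prior_count = prior_count)
  log2cpm_mean <- rowMeans(norm$log2cpm)
  mean_a <- rowMeans(norm$cpm[, ia, drop = FALSE])
  mean_b <- rowMeans(norm$cpm[, ib, drop = FALSE])
  log2fc <- log2(mean_b + prior_count) - log2(mean_a + prior_count)

  eq <- equalize_libsizes(cmm$counts, cmm$libsize)
  p <- nb_exact_test(eq[, ia, drop = FALSE], eq[, ib, drop = FALSE], phi)

  fdr <- rep(NA_real_, length(p))
  tested <- log2cpm_mean > floor_log2cpm
  fdr[tested] <- bh_adjust(p[tested])
  out <- data.frame(gene = rownames(cmm$counts), log2FC = log2fc,
                    log2CPM = log2cpm_mean, p = p, fdr = fdr,
                    row.names = NULL)
  attr(out, "contrast") <- c(model = model, ref = as.character(time_ref),
                             alt = as.character(time_alt))
  attr(out, "phi") <- phi
  attr(out, "floor_log2cpm") <- floor_log2cpm
  class(out) <- c("hsc_de", "data.frame")
  out
}

#' All later-vs-earlier pairwise DE tables for one model
#'
#' @inheritParams de_table
#' @return named list of [de_table()] results, one per ordered time pair,
#'   named `"<alt>_vs_<ref>"`.
#' @export
model_contrasts <- function(cm, model, phi = NULL, prior_count = 0.5,
                            floor_log2cpm = 2) {
  sel <- cm$samples$model == model
  if (!any(sel)) stopf("no samples for model '%s'", model)
  times <- sort(unique(cm$samples$time[sel]))
  if (length(times) < 2) stopf("model '%s' has fewer than 2 time points",
                               model)
  if (is.null(phi)) phi <- estimate_common_dispersion(subset_samples(cm, sel))
  out <- list()
  for (i in seq_along(times)[-length(times)]) {
    for (j in seq(i + 1, length(times))) {
      nm <- sprintf("%s_vs_%s", times[j], times[i])
      out[[nm]] <- de_table(cm, model, times[i], times[j], phi = phi,
                            prior_count = prior_count,
                            floor_log2cpm = floor_log2cpm)
    }
  }
  out
}

#' Global expression-distribution shift test
#'
#' Paired two-sided Wilcoxon signed-rank test on per-gene summary expression
#' (e.g. mean log2CPM) between an activated and a control condition, to
#' detect a genome-wide shift towards higher transcriptional activity.
#'
#' @param expr_control,expr_activated named per-gene summaries over the same
#'   gene universe.
#' @return list with `p.value`, `direction` ("up" means activated > control),
#'   `n` genes used.
#' @export
distribution_shift_test <- function(expr_control, expr_activated) {
  if (length(expr_control) != length(expr_activated))
    stopf("gene universes differ in length")
  if (!is.null(names(expr_control)) && !is.null(names(expr_activated))) {
    if (!identical(names(expr_control), names(expr_activated)))
      expr_activated <- expr_activated[names(expr_control)]
  }
  if (length(expr_control) < 10) stopf("need at least 10 genes")
  res <- signed_rank_test(expr_activated - expr_control, exact_max = 30)
  list(p.value = res$p.value, direction = res$direction,
       n = length(expr_control))
}
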