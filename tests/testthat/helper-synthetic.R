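# Shared small fixtures, built in code at test time.

# A reduced synthetic study: same design (three models, planted programs,
# motif coupling), fewer genes so tests run quickly.
small_config <- function(n_genes = 300, seed = 1, ...) {
  synthetic_config(n_genes = n_genes, seed = seed, ...)
}

# A minimal count container with two groups for DE tests.
two_group_counts <- function(counts_a, counts_b, libsize = NULL,
                             lengths = NULL) {
  counts <- cbind(counts_a, counts_b)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%04d", seq_len(nrow(counts)))
  na <- ncol(counts_a)
  samples <- data.frame(
    model = "M",
    time = rep(c(0, 1), c(na, ncol(counts_b))),
    replicate = c(seq_len(na), seq_len(ncol(counts_b))))
  colnames(counts) <- sprintf("s%d", seq_len(ncol(counts)))
  count_matrix(counts, samples, lengths = lengths, libsize = libsize)
}
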