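# Internal helpers shared across modules.

#' Derive a per-stage random seed from the master pipeline seed
#'
#' All randomness in a pipeline run flows from one master seed; each stage
#' draws from its own substream so that a stage re-run from cached upstream
#' outputs reproduces the full-run results exactly.
#'
#' @param seed master seed (integer).
#' @param stage stage index (small non-negative integer).
#' @return an integer seed, always below 2^31.
#' @keywords internal
stage_seed <- function(seed, stage) {
  as.integer((abs(as.numeric(seed)) + stage * 100003) %% 2147483629L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Row-wise sample variance of a matrix
#' @keywords internal
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}
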