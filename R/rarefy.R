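# One multivariate hypergeometric subsample of `depth` reads from integer
# `counts`: draw read indices without replacement, then map each index back
# to its feature via the cumulative count boundaries.
subsample_counts <- function(counts, depth) {
  total <- sum(counts)
  idx <- sample.int(total, depth)
  feat <- findInterval(idx, cumsum(counts), left.open = TRUE) + 1L
  tabulate(feat, nbins = length(counts))
}

#' Permuted rarefaction to a fixed read depth
#'
#' Repeatedly subsamples each sample's reads without replacement to exactly
#' `depth` reads, then averages the per-feature counts across the `n_perm`
#' subsamples and rounds to the nearest integer. Averaging repeated
#' rarefactions stabilizes the subsampled profile relative to a single draw.
#' Samples whose total count is below `depth` are dropped and reported via a
#' `"dropped_samples"` attribute (and a warning).
#'
#' @param table A [feature_table()] of integer counts.
#' @param depth Target depth (reads per sample), default 15000.
#' @param n_perm Number of independent subsamples to average, default 100.
#' @param seed Integer seed; required for reproducibility of the draws.
#' @return A [feature_table()] with the retained samples, each summing to
#'   `depth` up to rounding.
#' @export
rarefy_permuted <- function(table, depth = 15000, n_perm = 100, seed = NULL) {
  stopifnot(depth >= 1, n_perm >= 1)
  m <- ft_matrix(table)
  if (any(m != round(m))) abort("rarefy_permuted() requires integer counts.")
  totals <- rowSums(m)
  keep <- totals >= depth
  if (!any(keep)) abort(sprintf("All %d samples are below depth %d.", nrow(m), depth))
  if (any(!keep)) {
    warn(sprintf("Dropping %d sample(s) below depth %d: %s",
                 sum(!keep), depth,
                 paste(rownames(m)[!keep], collapse = ", ")))
  }
  m <- m[keep, , drop = FALSE]
  out <- with_seed_(seed, {
    t(apply(m, 1, function(counts) {
      if (sum(counts) == depth) return(counts)
      acc <- numeric(length(counts))
      for (k in seq_len(n_perm)) acc <- acc + subsample_counts(counts, depth)
      round(acc / n_perm)
    }))
  })
  dimnames(out) <- dimnames(m)
  res <- feature_table(out, kind = ft_kind(table))
  attr(res, "dropped_samples") <- rownames(ft_matrix(table))[!keep]
  res
}
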