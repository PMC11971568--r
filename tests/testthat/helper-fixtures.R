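# Shared fixtures and independent oracles, built in code at test time.

# tiny feature table: counts, ids s1..sn / f1..fm
make_ft <- function(values, kind = "taxonomic") {
  m <- as.matrix(values)
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  feature_table(m, kind = kind)
}

# minimal metadata for one treatment stratum: n donor reps per donor at each
# time, n mixture reps, ids "<label>_t<t>_r<r>"
make_meta <- function(donors = c("A", "B"), treatment = "AxB",
                      times = 1, n_don = 2, n_mix = 2, dilution = 1e-1) {
  rows <- list()
  for (t in times) {
    for (dl in donors) {
      for (r in seq_len(n_don)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          sample_id = sprintf("%s_t%s_r%s", dl, t, r), role = "donor",
          soil_label = dl, treatment = NA_character_, dilution = dilution,
          time_days = t, replicate = as.character(r))
      }
    }
    for (r in seq_len(n_mix)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = sprintf("%s_t%s_r%s", treatment, t, r), role = "mixture",
        soil_label = NA_character_, treatment = treatment, dilution = dilution,
        time_days = t, replicate = as.character(r))
    }
  }
  dplyr::bind_rows(rows)
}

# exact Mann-Whitney one/two-sided p by full enumeration of rank splits
mw_enum_p <- function(a, b, alternative = "two_sided") {
  n_a <- length(a)
  pooled <- c(a, b)
  u_stat <- function(idx) {
    aa <- pooled[idx]; bb <- pooled[-idx]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  }
  u_obs <- u_stat(seq_len(n_a))
  splits <- utils::combn(length(pooled), n_a)
  us <- apply(splits, 2, u_stat)
  switch(alternative,
         less = mean(us <= u_obs),
         greater = mean(us >= u_obs),
         two_sided = min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs))))
}

# brute-force EMD over all transport plans on a 1/K grid (independent of the
# simplex solver): recursively enumerate integer allocation matrices
emd_enum <- function(p, q, cost, K) {
  sp <- round(p * K); dq <- round(q * K)
  stopifnot(sum(sp) == sum(dq))
  best <- Inf
  m <- length(sp); n <- length(dq)
  rec <- function(i, remaining_d, acc) {
    if (acc >= best) return()
    if (i > m) { best <<- min(best, acc); return() }
    # enumerate allocations of supply sp[i] over the n demands
    alloc_rec <- function(j, left, rem, acc2) {
      if (acc2 >= best) return()
      if (j == n) {
        if (left <= rem[n]) {
          rem[n] <- rem[n] - left
          rec(i + 1L, rem, acc2 + left * cost[i, n])
        }
        return()
      }
      for (x in 0:min(left, rem[j])) {
        rem2 <- rem; rem2[j] <- rem2[j] - x
        alloc_rec(j + 1L, left - x, rem2, acc2 + x * cost[i, j])
      }
    }
    alloc_rec(1L, sp[i], remaining_d, acc)
  }
  rec(1L, dq, 0)
  best / K
}

# PERMANOVA p by full enumeration of distinct label assignments
permanova_enum_p <- function(dm, groups) {
  m <- as.matrix(dm)^2
  f_of <- function(g) {
    n <- nrow(m); lv <- unique(g)
    ss_tot <- sum(m[upper.tri(m)]) / n
    ss_w <- 0
    for (l in lv) {
      idx <- which(g == l)
      sub <- m[idx, idx, drop = FALSE]
      ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
    }
    ((ss_tot - ss_w) / (length(lv) - 1)) / (ss_w / (n - length(lv)))
  }
  f_obs <- f_of(groups)
  lv <- unique(groups)
  stopifnot(length(lv) == 2)
  n1 <- sum(groups == lv[1])
  splits <- utils::combn(length(groups), n1)
  fs <- apply(splits, 2, function(idx) {
    g <- rep(lv[2], length(groups)); g[idx] <- lv[1]
    f_of(g)
  })
  mean(fs >= f_obs - 1e-12)
}
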