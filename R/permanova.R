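#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance for a single grouping
#' factor. Sums of squares are computed directly from the distance matrix:
#' \deqn{SS_{total} = \frac{1}{n}\sum_{i<j} d_{ij}^2, \qquad
#'       SS_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2,}
#' \eqn{SS_{between} = SS_{total} - SS_{within}}, and the pseudo-F statistic
#' is \eqn{(SS_{between}/(g-1)) / (SS_{within}/(n-g))}. Significance comes
#' from random permutations of the group labels, with the add-one estimator
#' \eqn{p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})} so p is never zero.
#'
#' @param dm A `coalescr_dist` (or symmetric distance matrix with ids).
#' @param groups Group labels: either a vector aligned with the matrix rows,
#'   or a named vector / two-column data frame (`sample_id`, `group`).
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return A `coalescr_permanova` object with fields `pseudo_F`, `R2`,
#'   `p_value`, `n_permutations`, `group_sizes`, `seed`.
#' @export
permanova <- function(dm, groups, n_permutations = 999, seed = NULL) {
  m <- as.matrix(dm)
  n <- nrow(m)
  groups <- resolve_groups(groups, rownames(m))
  sizes <- table(groups)
  if (length(sizes) < 2) abort("PERMANOVA needs at least 2 groups.")
  if (any(sizes < 2)) {
    abort(sprintf("Every group needs >= 2 samples; singleton group(s): %s",
                  paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  d2 <- m^2
  f_obs <- permanova_f(d2, groups)
  perm_f <- with_seed_(seed, {
    vapply(seq_len(n_permutations), function(i) {
      permanova_f(d2, sample(groups))$f
    }, numeric(1))
  })
  structure(
    list(pseudo_F = f_obs$f, R2 = f_obs$r2,
         p_value = (1 + sum(perm_f >= f_obs$f)) / (1 + n_permutations),
         n_permutations = n_permutations,
         group_sizes = as.integer(sizes),
         group_names = names(sizes),
         metric = attr(dm, "metric") %||% "unknown",
         seed = seed),
    class = "coalescr_permanova"
  )
}

resolve_groups <- function(groups, ids) {
  if (is.data.frame(groups)) {
    if (!all(c("sample_id", "group") %in% names(groups))) {
      abort("Group data frame needs columns `sample_id` and `group`.")
    }
    groups <- setNames(as.character(groups$group), groups$sample_id)
  }
  if (!is.null(names(groups)) && all(nzchar(names(groups)))) {
    missing <- setdiff(ids, names(groups))
    if (length(missing) > 0L) {
      abort(sprintf("No group label for sample(s): %s",
                    paste(missing, collapse = ", ")))
    }
    groups <- groups[ids]
  } else if (length(groups) != length(ids)) {
    abort(sprintf("`groups` (length %d) does not match the %d samples.",
                  length(groups), length(ids)))
  }
  as.character(groups)
}

permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  g <- length(unique(groups))
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (lvl in unique(groups)) {
    idx <- which(groups == lvl)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  f <- (ss_between / (g - 1)) / (ss_within / (n - g))
  list(f = f, r2 = ss_between / ss_total)
}

#' @export
print.coalescr_permanova <- function(x, ...) {
  cat(sprintf("<coalescr_permanova> metric = %s\n", x$metric))
  cat(sprintf("groups: %s (n = %s)\n",
              paste(x$group_names, collapse = ", "),
              paste(x$group_sizes, collapse = ", ")))
  cat(sprintf("pseudo-F = %.4g, R2 = %.4f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$R2, x$p_value, x$n_permutations))
  invisible(x)
}

#' @rdname permanova
#' @param x,object A `coalescr_permanova`.
#' @param ... Unused.
#' @method tidy coalescr_permanova
#' @export
tidy.coalescr_permanova <- function(x, ...) {
  tibble(term = "group", pseudo_F = x$pseudo_F, R2 = x$R2,
         p_value = x$p_value, n_permutations = x$n_permutations)
}

#' @rdname permanova
#' @method glance coalescr_permanova
#' @export
glance.coalescr_permanova <- function(x, ...) {
  tibble(pseudo_F = x$pseudo_F, R2 = x$R2, p_value = x$p_value,
         n_groups = length(x$group_sizes), n_samples = sum(x$group_sizes),
         n_permutations = x$n_permutations)
}
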