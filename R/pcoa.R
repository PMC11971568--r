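#' Principal coordinates analysis (classical metric MDS)
#'
#' Double-centers the squared distance matrix and eigendecomposes it. Axes
#' are ordered by decreasing eigenvalue; coordinates are returned for the
#' first `k` axes with positive eigenvalues. Negative eigenvalues (which
#' arise for non-Euclidean dissimilarities) are reported, not silently
#' dropped, and the proportion of variation explained uses the sum of
#' positive eigenvalues as the denominator.
#'
#' @param dm A `coalescr_dist` (or symmetric matrix with ids).
#' @param k Number of axes, `1 <= k < n`.
#' @return A `coalescr_pcoa` object: list with `coordinates` (tibble
#'   `sample_id`, `axis1..axisk`), `eigenvalues` (all n), and
#'   `prop_explained` (per returned axis).
#' @export
pcoa <- function(dm, k = 2) {
  m <- as.matrix(dm)
  n <- nrow(m)
  if (k < 1 || k >= n) abort(sprintf("`k` must be in [1, %d); got %s.", n, k))
  j <- diag(n) - 1 / n
  b <- -0.5 * j %*% m^2 %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  eig <- e$values
  pos <- which(eig > max(eig) * 1e-12 & eig > 0)
  k_eff <- min(k, length(pos))
  if (k_eff == 0L) abort("No positive eigenvalues; the input has no metric structure.")
  coords <- e$vectors[, pos[seq_len(k_eff)], drop = FALSE] %*%
    diag(sqrt(eig[pos[seq_len(k_eff)]]), k_eff)
  colnames(coords) <- paste0("axis", seq_len(k_eff))
  structure(
    list(
      coordinates = dplyr::bind_cols(tibble(sample_id = rownames(m)),
                                     tibble::as_tibble(coords)),
      eigenvalues = eig,
      prop_explained = eig[pos[seq_len(k_eff)]] / sum(eig[pos]),
      metric = attr(dm, "metric") %||% "unknown"
    ),
    class = "coalescr_pcoa"
  )
}

#' @export
print.coalescr_pcoa <- function(x, ...) {
  cat(sprintf("<coalescr_pcoa> %d samples, metric = %s\n",
              nrow(x$coordinates), x$metric))
  cat(sprintf("axes: %s\n",
              paste(sprintf("%.1f%%", 100 * x$prop_explained), collapse = ", ")))
  neg <- sum(x$eigenvalues < 0)
  if (neg > 0) cat(sprintf("%d negative eigenvalue(s), min %.3g\n",
                           neg, min(x$eigenvalues)))
  invisible(x)
}

#' @rdname pcoa
#' @param x A `coalescr_pcoa`.
#' @param ... Unused.
#' @method tidy coalescr_pcoa
#' @export
tidy.coalescr_pcoa <- function(x, ...) x$coordinates

#' Ordination plot for a PCoA result
#'
#' @param object A `coalescr_pcoa`.
#' @param colour_by Optional tibble (`sample_id` + one grouping column) or a
#'   character vector aligned with the samples, used to colour points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coalescr_pcoa
#' @export
autoplot.coalescr_pcoa <- function(object, colour_by = NULL, ...) {
  df <- object$coordinates
  if (!"axis2" %in% names(df)) df$axis2 <- 0
  lab <- function(i) sprintf("Axis %d (%.1f%%)", i, 100 * object$prop_explained[i])
  if (!is.null(colour_by)) {
    if (is.data.frame(colour_by)) {
      df <- dplyr::left_join(df, colour_by, by = "sample_id")
      grp <- setdiff(names(colour_by), "sample_id")[1]
    } else {
      df$group <- colour_by
      grp <- "group"
    }
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$axis1, .data$axis2,
                                          colour = .data[[grp]]))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$axis1, .data$axis2))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = lab(1),
                  y = if (length(object$prop_explained) > 1) lab(2) else "Axis 2",
                  title = sprintf("PCoA (%s)", object$metric)) +
    ggplot2::theme_minimal()
}
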