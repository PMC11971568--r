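# Distance metrics for community profiles. JSD, Bray-Curtis, Euclidean,
# cosine and Earth Mover's distance, pairwise distance matrices, and their
# (de)serialization.

normalize_probs <- function(x, name) {
  assert_numeric_vector(x, name)
  assert_nonnegative(x, name)
  s <- sum(x)
  if (s <= 0) abort(sprintf("`%s` must have a positive sum.", name))
  x / s
}

#' Jensen-Shannon divergence between two profiles
#'
#' Profiles are normalized to relative abundances, then
#' \eqn{JS(p,q) = \frac12 KL(p\|m) + \frac12 KL(q\|m)} with
#' \eqn{m = \frac12(p+q)} and the convention \eqn{0\log 0 = 0}. Because every
#' coordinate of \eqn{m} is positive wherever \eqn{p} or \eqn{q} is, no
#' pseudocounts are needed. The default variant returns the square root of
#' the base-2 divergence, a true metric bounded in \[0, 1\]; the raw
#' divergence in bits or nats can be requested instead. The variant is
#' recorded as an attribute on results that carry JSD values.
#'
#' @param p,q Nonnegative numeric vectors of equal length with positive sums.
#' @param variant `"sqrt_base2"` (default), `"divergence_base2"` or
#'   `"divergence_nats"`.
#' @return A nonnegative scalar (in \[0, 1\] for the base-2 variants).
#' @export
#' @examples
#' jsd(c(0.5, 0.5), c(1, 0))                      # 0.5579...
#' jsd(c(0.5, 0.5), c(1, 0), "divergence_base2")  # 0.31128
jsd <- function(p, q, variant = c("sqrt_base2", "divergence_base2", "divergence_nats")) {
  variant <- match.arg(variant)
  assert_same_length(p, q, "p", "q")
  p <- normalize_probs(p, "p")
  q <- normalize_probs(q, "q")
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  div_nats <- kl(p, m) / 2 + kl(q, m) / 2
  switch(variant,
         divergence_nats = div_nats,
         divergence_base2 = div_nats / log(2),
         sqrt_base2 = sqrt(max(div_nats / log(2), 0)))
}

#' Bray-Curtis dissimilarity
#'
#' \eqn{\sum_i |x_i - y_i| / \sum_i (x_i + y_i)}, bounded in \[0, 1\].
#'
#' @param x,y Nonnegative numeric vectors of equal length, not both all-zero.
#' @return A scalar in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  assert_same_length(x, y, "x", "y")
  assert_numeric_vector(x, "x"); assert_numeric_vector(y, "y")
  assert_nonnegative(x, "x"); assert_nonnegative(y, "y")
  denom <- sum(x + y)
  if (denom <= 0) abort("Both vectors are all-zero; Bray-Curtis is undefined.")
  sum(abs(x - y)) / denom
}

#' Euclidean and cosine distances
#'
#' @param x,y Numeric vectors of equal length. Cosine distance
#'   \eqn{1 - x\cdot y / (\|x\|\|y\|)} requires both norms to be positive.
#' @return Euclidean: a nonnegative scalar. Cosine: a scalar in \[0, 2\]
#'   (\[0, 1\] for nonnegative vectors).
#' @export
euclidean <- function(x, y) {
  assert_same_length(x, y, "x", "y")
  assert_numeric_vector(x, "x"); assert_numeric_vector(y, "y")
  sqrt(sum((x - y)^2))
}

#' @rdname euclidean
#' @export
cosine_distance <- function(x, y) {
  assert_same_length(x, y, "x", "y")
  assert_numeric_vector(x, "x"); assert_numeric_vector(y, "y")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) abort("Cosine distance is undefined for a zero vector.")
  1 - sum(x * y) / (nx * ny)
}

#' Earth Mover's distance between two profiles
#'
#' With the default unit ground cost (1 between any two distinct features, 0
#' on the diagonal), the optimal transport cost between probability vectors
#' reduces to total variation, \eqn{\frac12\sum_i |p_i - q_i|}, and is
#' computed in closed form. With a user-supplied ground metric (e.g. a
#' phylogenetic distance between features), the transportation problem is
#' solved exactly with a transportation-simplex solver.
#'
#' @param p,q Nonnegative numeric vectors of equal length with positive sums
#'   (normalized internally to sum 1).
#' @param ground_distance Optional feature-by-feature cost matrix: nonnegative,
#'   symmetric, zero diagonal.
#' @return The minimal transport cost (nonnegative scalar).
#' @export
#' @examples
#' emd(c(1, 0), c(0, 1))                       # 1
#' d <- abs(outer(0:2, 0:2, "-"))              # 1-D index ground distance
#' emd(c(0.5, 0.5, 0), c(0, 0.5, 0.5), d)      # 0.5
emd <- function(p, q, ground_distance = NULL) {
  assert_same_length(p, q, "p", "q")
  p <- normalize_probs(p, "p")
  q <- normalize_probs(q, "q")
  if (is.null(ground_distance)) {
    return(sum(abs(p - q)) / 2)
  }
  gd <- as.matrix(ground_distance)
  n <- length(p)
  if (!all(dim(gd) == c(n, n))) {
    abort(sprintf("`ground_distance` must be %d x %d; got %d x %d.",
                  n, n, nrow(gd), ncol(gd)))
  }
  if (any(gd < 0)) abort("`ground_distance` must be nonnegative.")
  if (max(abs(gd - t(gd))) > 1e-12) abort("`ground_distance` must be symmetric.")
  if (any(abs(diag(gd)) > 1e-12)) abort("`ground_distance` must have a zero diagonal.")
  # only bins carrying mass participate in transport
  si <- which(p > 0); di <- which(q > 0)
  solve_transport(p[si], q[di], gd[si, di, drop = FALSE])
}

# Exact transportation problem: minimize sum(F * cost) subject to
# rowSums(F) = supply, colSums(F) = demand, F >= 0.
# Northwest-corner initial basis, then MODI (u-v potential) pivoting.
solve_transport <- function(supply, demand, cost) {
  m <- length(supply); n <- length(demand)
  alloc <- matrix(0, m, n)
  basis <- matrix(FALSE, m, n)
  # northwest corner rule; keeps exactly m + n - 1 basic cells (some may be 0)
  s <- supply; d <- demand
  i <- 1L; j <- 1L
  repeat {
    x <- min(s[i], d[j])
    alloc[i, j] <- x
    basis[i, j] <- TRUE
    s[i] <- s[i] - x; d[j] <- d[j] - x
    if (i == m && j == n) break
    if (s[i] <= d[j] && i < m) i <- i + 1L else j <- j + 1L
  }
  max_iter <- 200L * m * n + 1000L
  for (iter in seq_len(max_iter)) {
    uv <- transport_potentials(basis, cost)
    red <- cost - outer(uv$u, rep(1, n)) - outer(rep(1, m), uv$v)
    red[basis] <- 0
    enter <- which(red < -1e-10, arr.ind = TRUE)
    if (nrow(enter) == 0L) break
    # most negative reduced cost enters
    k <- which.min(red[enter])
    ei <- enter[k, 1]; ej <- enter[k, 2]
    cyc <- transport_cycle(basis, ei, ej)
    minus <- cyc[seq(2, nrow(cyc), by = 2), , drop = FALSE]
    theta_vals <- alloc[minus]
    theta <- min(theta_vals)
    leave <- minus[which.min(theta_vals), , drop = FALSE]
    sgn <- rep(c(1, -1), length.out = nrow(cyc))
    alloc[cyc] <- alloc[cyc] + sgn * theta
    basis[ei, ej] <- TRUE
    basis[leave] <- FALSE
    alloc[leave] <- 0
    if (iter == max_iter) abort("Transportation simplex failed to converge.")
  }
  sum(alloc * cost)
}

# Solve u_i + v_j = cost_ij over the basis spanning tree (u_1 = 0).
transport_potentials <- function(basis, cost) {
  m <- nrow(basis); n <- ncol(basis)
  u <- rep(NA_real_, m); v <- rep(NA_real_, n)
  u[1] <- 0
  repeat {
    progressed <- FALSE
    for (cell in which(basis)) {
      i <- (cell - 1L) %% m + 1L
      j <- (cell - 1L) %/% m + 1L
      if (!is.na(u[i]) && is.na(v[j])) { v[j] <- cost[i, j] - u[i]; progressed <- TRUE }
      else if (is.na(u[i]) && !is.na(v[j])) { u[i] <- cost[i, j] - v[j]; progressed <- TRUE }
    }
    if (!anyNA(u) && !anyNA(v)) break
    if (!progressed) abort("Degenerate transportation basis: disconnected spanning tree.")
  }
  list(u = u, v = v)
}

# Unique alternating cycle created by adding cell (ei, ej) to the basis tree:
# breadth-first search from column node ej back to row node ei over basis
# cells, alternating row/column moves. Returns the cycle as an ordered
# (row, col) index matrix starting at the entering cell.
transport_cycle <- function(basis, ei, ej) {
  m <- nrow(basis); n <- ncol(basis)
  # nodes: rows 1..m, cols m+1..m+n; edges = basic cells
  adj <- vector("list", m + n)
  for (cell in which(basis)) {
    i <- (cell - 1L) %% m + 1L
    j <- (cell - 1L) %/% m + 1L
    adj[[i]] <- c(adj[[i]], m + j)
    adj[[m + j]] <- c(adj[[m + j]], i)
  }
  # path from node (m + ej) to node ei through the tree
  parent <- rep(NA_integer_, m + n)
  start <- m + ej
  parent[start] <- start
  queue <- start
  while (length(queue) > 0L) {
    node <- queue[1]; queue <- queue[-1]
    if (node == ei) break
    for (nb in adj[[node]]) {
      if (is.na(parent[nb])) { parent[nb] <- node; queue <- c(queue, nb) }
    }
  }
  if (is.na(parent[ei])) abort("Transportation basis is not a spanning tree.")
  path <- ei
  while (path[length(path)] != start) path <- c(path, parent[path[length(path)]])
  # path alternates row, col, row, col...; convert node pairs to cells
  cells <- matrix(0L, 0, 2)
  prev <- ei
  for (node in path[-1]) {
    cell <- if (prev <= m) c(prev, node - m) else c(node, prev - m)
    cells <- rbind(cells, cell)
    prev <- node
  }
  rbind(c(ei, ej), cells)
}

metric_registry <- function() {
  list(
    jsd = function(x, y, ...) jsd(x, y, ...),
    bray_curtis = function(x, y, ...) bray_curtis(x, y),
    euclidean = function(x, y, ...) euclidean(x, y),
    cosine = function(x, y, ...) cosine_distance(x, y),
    emd = function(x, y, ...) emd(x, y, ...)
  )
}

# Metrics that interpret rows as probability distributions.
probabilistic_metrics <- c("jsd", "emd")

#' Pairwise distance matrix over all samples of a feature table
#'
#' For probabilistic metrics (`jsd`, `emd`) each row is normalized to relative
#' abundances before the metric is applied; `bray_curtis`, `euclidean` and
#' `cosine` operate on the raw values. Abiotic tables (kind `"abiotic"`) are
#' transformed first: per-variable z-scores for `euclidean` (matching
#' PERMANOVA-on-Euclidean usage) and per-variable min-max scaling to \[0, 1\]
#' followed by row normalization for the probabilistic metrics, so that
#' mixed-unit soil chemistry becomes comparable.
#'
#' @param table A [feature_table()].
#' @param metric One of `"jsd"`, `"bray_curtis"`, `"euclidean"`, `"cosine"`,
#'   `"emd"`.
#' @param ... Metric options (`variant` for `jsd`, `ground_distance` for
#'   `emd`).
#' @return A `coalescr_dist` object: a symmetric matrix with zero diagonal,
#'   sample ids as dimnames, and the metric name (plus options) as attributes.
#' @export
pairwise_distances <- function(table,
                               metric = c("jsd", "bray_curtis", "euclidean", "cosine", "emd"),
                               ...) {
  metric <- match.arg(metric)
  m <- ft_matrix(table)
  m <- prepare_metric_input(m, metric, ft_kind(table))
  fun <- metric_registry()[[metric]]
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d[i, j] <- d[j, i] <- fun(m[i, ], m[j, ], ...)
      }
    }
  }
  dist_matrix(d, metric, options = list(...))
}

prepare_metric_input <- function(m, metric, kind) {
  if (kind == "abiotic") {
    if (metric %in% probabilistic_metrics) {
      rng <- apply(m, 2, range)
      span <- rng[2, ] - rng[1, ]
      span[span == 0] <- 1
      m <- sweep(sweep(m, 2, rng[1, ], "-"), 2, span, "/")
      # a sample sitting at the per-variable minimum everywhere would scale
      # to an all-zero row; a vanishing pseudocount keeps it normalizable
      m <- m + 1e-6
    } else if (metric == "euclidean") {
      m <- scale(m)
      m[, attr(m, "scaled:scale") == 0] <- 0
      m <- m[, , drop = FALSE]
    }
  }
  if (metric %in% probabilistic_metrics) {
    rs <- rowSums(m)
    if (any(rs <= 0)) {
      abort(sprintf("Sample(s) with nonpositive total cannot be normalized: %s",
                    paste(rownames(m)[rs <= 0], collapse = ", ")))
    }
    m <- m / rs
  }
  m
}

#' Distance matrix container
#'
#' @param values Symmetric nonnegative matrix with zero diagonal and sample
#'   ids as dimnames.
#' @param metric Metric name.
#' @param options Metric options used (recorded for provenance).
#' @return A `coalescr_dist` object.
#' @export
dist_matrix <- function(values, metric, options = list()) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) abort("Distance matrix needs sample ids as dimnames.")
  if (nrow(values) != ncol(values)) abort("Distance matrix must be square.")
  if (max(abs(values - t(values))) > 1e-12) abort("Distance matrix must be symmetric.")
  if (any(abs(diag(values)) > 1e-12)) abort("Distance matrix diagonal must be zero.")
  if (any(values < 0)) abort("Distances must be nonnegative.")
  structure(values,
            metric = metric,
            metric_options = options[lengths(options) > 0],
            class = c("coalescr_dist", "matrix", "array"))
}

#' @export
print.coalescr_dist <- function(x, ...) {
  cat(sprintf("<coalescr_dist> %d samples, metric = %s\n",
              nrow(x), attr(x, "metric")))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))), drop = FALSE])
  if (nrow(x) > 6) cat(sprintf("... %d more samples\n", nrow(x) - 6))
  invisible(x)
}

#' Tidy a distance matrix into long format
#'
#' @param x A `coalescr_dist`.
#' @param ... Unused.
#' @return A tibble with one row per unordered sample pair: `sample_i`,
#'   `sample_j`, `metric`, `value`.
#' @method tidy coalescr_dist
#' @export
tidy.coalescr_dist <- function(x, ...) {
  ids <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(sample_i = ids[idx[, 1]],
         sample_j = ids[idx[, 2]],
         metric = attr(x, "metric"),
         value = x[idx])
}

#' Read/write a distance matrix as square TSV
#'
#' @param x A `coalescr_dist` (for writing).
#' @param path File path; first column holds sample ids, header the same ids.
#' @param metric Metric name to attach when reading.
#' @export
write_dist_matrix <- function(x, path) {
  df <- tibble::as_tibble(unclass(x), rownames = "sample_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_dist_matrix
#' @export
read_dist_matrix <- function(path, metric = "unknown") {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- as.character(df[[1]])
  dist_matrix(m, metric)
}

# Extract d(a, b) for vectors of ids; errors on unknown ids.
dist_lookup <- function(dm, a, b) {
  ids <- rownames(dm)
  bad <- setdiff(unique(c(a, b)), ids)
  if (length(bad) > 0L) {
    abort(sprintf("Sample id(s) absent from distance matrix: %s",
                  paste(bad, collapse = ", ")))
  }
  unclass(dm)[cbind(match(a, ids), match(b, ids))]
}
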