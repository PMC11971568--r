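test_that("hand-derived metric values are reproduced", {
  # JSD of (.5,.5) vs (1,0): KL terms against m = (.75,.25)
  expect_equal(jsd(c(0.5, 0.5), c(1, 0), "divergence_base2"), 0.31128, tolerance = 1e-4)
  expect_equal(jsd(c(0.5, 0.5), c(1, 0)), 0.5579, tolerance = 1e-4)
  expect_equal(jsd(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), 1)          # disjoint support saturates
  expect_equal(jsd(c(3, 7), c(30, 70)), 0)         # scale invariance

  expect_equal(bray_curtis(c(2, 2, 6), c(4, 2, 4)), 0.2)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)
  expect_equal(euclidean(c(3, 4), c(0, 0)), 5)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(emd(c(1, 0), c(0, 1)), 1)
  gd <- abs(outer(0:2, 0:2, "-"))
  expect_equal(emd(c(0.5, 0.5, 0), c(0, 0.5, 0.5), gd), 1)
})

test_that("metric preconditions error informatively", {
  expect_error(jsd(c(1, 2), c(1, 2, 3)), "length")
  expect_error(jsd(c(0, 0), c(1, 0)), "positive sum")
  expect_error(jsd(c(-1, 2), c(1, 0)), "negative")
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(cosine_distance(c(0, 0), c(1, 1)), "zero vector")
  expect_error(emd(c(1, 0), c(0, 1), matrix(1, 3, 3)), "2 x 2")
  expect_error(emd(c(1, 0), c(0, 1), matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("metric axioms hold on random nonnegative vectors", {
  set.seed(11)
  metrics <- list(jsd = jsd, bray_curtis = bray_curtis, euclidean = euclidean,
                  cosine = cosine_distance, emd = emd)
  for (rep in 1:25) {
    x <- rgamma(8, 0.5) + 1e-6
    y <- rgamma(8, 0.5) + 1e-6
    z <- rgamma(8, 0.5) + 1e-6
    for (nm in names(metrics)) {
      f <- metrics[[nm]]
      expect_gte(f(x, y), 0)
      expect_equal(f(x, y), f(y, x), tolerance = 1e-12)
      expect_equal(f(x, x), 0, tolerance = 1e-12)
    }
    # triangle inequality for the true metrics
    for (nm in c("jsd", "euclidean", "emd")) {
      f <- metrics[[nm]]
      expect_lte(f(x, z), f(x, y) + f(y, z) + 1e-10)
    }
    # boundedness
    expect_lte(jsd(x, y), 1)
    expect_lte(jsd(x, y, "divergence_base2"), 1)
    expect_lte(bray_curtis(x, y), 1)
  }
})

test_that("EMD through the simplex solver matches the closed forms and brute force", {
  set.seed(23)
  # explicit unit-cost matrix exercises the solver; must equal total variation
  unit8 <- 1 - diag(8)
  for (rep in 1:50) {
    p <- rgamma(8, 0.4); p <- p / sum(p)
    q <- rgamma(8, 0.4); q <- q / sum(q)
    expect_equal(emd(p, q, unit8), sum(abs(p - q)) / 2, tolerance = 1e-10)
  }
  # metric ground cost on <= 4 bins vs exhaustive enumeration of plans
  for (rep in 1:10) {
    nb <- sample(3:4, 1)
    K <- 8
    p <- as.vector(rmultinom(1, K, rep(1, nb))) / K
    q <- as.vector(rmultinom(1, K, rep(1, nb))) / K
    pts <- sort(runif(nb, 0, 5))
    gd <- abs(outer(pts, pts, "-"))
    expect_equal(emd(p, q, gd), emd_enum(p, q, gd, K), tolerance = 1e-10)
  }
  # triangle inequality with a metric ground cost
  pts <- c(0, 1, 3, 7)
  gd <- abs(outer(pts, pts, "-"))
  for (rep in 1:20) {
    p <- rgamma(4, 0.5); q <- rgamma(4, 0.5); r <- rgamma(4, 0.5)
    expect_lte(emd(p, r, gd), emd(p, q, gd) + emd(q, r, gd) + 1e-10)
  }
})

test_that("pairwise_distances builds a consistent symmetric matrix", {
  set.seed(5)
  ft <- make_ft(matrix(rpois(4 * 6, 20), 4, 6))
  m <- as.matrix(tibble::as_tibble(ft)[-1])
  for (metric in c("jsd", "bray_curtis", "euclidean", "cosine", "emd")) {
    dm <- pairwise_distances(ft, metric)
    expect_s3_class(dm, "coalescr_dist")
    expect_equal(unclass(dm), t(unclass(dm)), ignore_attr = TRUE)
    expect_true(all(diag(dm) == 0))
    expect_true(all(dm >= 0))
  }
  dm <- pairwise_distances(ft, "jsd")
  expect_equal(dm["s1", "s3"], jsd(m[1, ], m[3, ]))
  # identical samples -> zero entries
  ft2 <- make_ft(rbind(c(1, 2, 3), c(1, 2, 3)))
  expect_true(all(pairwise_distances(ft2, "jsd") == 0))
  # long-format tidy and square TSV round-trip
  td <- tidy(dm)
  expect_equal(nrow(td), choose(4, 2))
  expect_equal(td$value[td$sample_i == "s1" & td$sample_j == "s3"], dm["s1", "s3"])
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dist_matrix(dm, f)
  back <- read_dist_matrix(f, metric = "jsd")
  expect_equal(unclass(back), unclass(dm), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("abiotic tables are rescaled before probabilistic metrics", {
  ab <- make_ft(cbind(pH = c(4, 5, 6), OM = c(100, 220, 160)), kind = "abiotic")
  dm <- pairwise_distances(ab, "jsd")
  # min-max scaling maps both variables onto [0, 1]: the huge-unit variable
  # cannot dominate, and distances stay finite and bounded
  expect_true(all(is.finite(dm)))
  expect_true(all(dm <= 1))
  # euclidean on abiotic kind z-scores the variables: scale-invariant
  ab2 <- make_ft(cbind(pH = c(4, 5, 6), OM = 1000 * c(100, 220, 160)),
                 kind = "abiotic")
  expect_equal(unclass(pairwise_distances(ab2, "euclidean")),
               unclass(pairwise_distances(ab, "euclidean")),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("PCoA reproduces Euclidean configurations and reports negative eigenvalues", {
  # points on a line: axis 1 recovers the spacing up to sign/translation
  x <- c(0, 1, 4, 9)
  dx <- as.matrix(dist(x))
  dimnames(dx) <- list(paste0("s", 1:4), paste0("s", 1:4))
  p <- pcoa(dist_matrix(dx, "euclidean"), k = 1)
  ax <- p$coordinates$axis1
  expect_equal(abs(cor(ax, x)), 1, tolerance = 1e-8)

  # 2-D point set: recovered coordinates reproduce the distance matrix
  set.seed(31)
  pts <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("s", 1:6), NULL))
  dm2 <- dist_matrix(as.matrix(dist(pts)), "euclidean")
  p2 <- pcoa(dm2, k = 2)
  rec <- as.matrix(p2$coordinates[-1])
  expect_equal(unname(as.matrix(dist(rec))), unname(as.matrix(dist(pts))),
               tolerance = 1e-8)

  # all-equal distances among 3 samples: two equal positive eigenvalues
  eq <- matrix(1, 3, 3) - diag(3)
  dimnames(eq) <- list(letters[1:3], letters[1:3])
  p3 <- pcoa(dist_matrix(eq, "unit"), k = 2)
  pos <- p3$eigenvalues[p3$eigenvalues > 1e-10]
  expect_equal(length(pos), 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-10)

  # non-Euclidean input: negative eigenvalues are reported
  tri <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3)
  tri[1, 2] <- tri[2, 1] <- 1.9  # violates the Euclidean embedding
  dimnames(tri) <- list(letters[1:3], letters[1:3])
  p4 <- pcoa(dist_matrix(tri, "odd"), k = 1)
  expect_true(any(p4$eigenvalues < 0))
  expect_error(pcoa(dm2, k = 6), "k")
})
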