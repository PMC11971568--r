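# fixture: one stratum where mixture replicates duplicate donor A's profile
identity_fixture <- function(times = 1, n_don = 3, n_mix = 3) {
  meta <- make_meta(times = times, n_don = n_don, n_mix = n_mix)
  profA <- c(10, 20, 30, 40)
  profB <- c(40, 30, 20, 10)
  rows <- lapply(seq_len(nrow(meta)), function(i) {
    r <- meta[i, ]
    if (r$role == "mixture" || r$soil_label == "A") profA else profB
  })
  m <- do.call(rbind, rows)
  rownames(m) <- meta$sample_id
  colnames(m) <- paste0("f", 1:4)
  list(table = feature_table(m), meta = meta)
}

# lookup helper living in the test: reads entries straight off the matrix
dist_lookup_public <- function(dm, a, b) {
  ids <- rownames(as.matrix(dm))
  unclass(dm)[cbind(match(a, ids), match(b, ids))]
}

test_that("donor-outcome distances emit the full replicate cross-product per stratum", {
  cfg <- scenario_config(n_features = 60, sequencing_depth = 1500, seed = 101)
  sim <- simulate_experiment(cfg)
  recs <- donor_outcome_distances(sim$table, sim$meta, metric = "jsd")
  # 2 donors x 4 times x (6 donor reps x 6 mixture reps)
  expect_equal(nrow(recs), 2 * 4 * 36)
  counts <- dplyr::count(recs, .data$time_days, .data$donor_label)
  expect_true(all(counts$n == 36))
  expect_true(all(recs$distance >= 0))

  # matrix entries match single-pair metric calls through pairwise_distances
  dm <- pairwise_distances(sim$table, "jsd")
  expect_equal(recs$distance,
               dist_lookup_public(dm, recs$donor_sample_id, recs$mixture_sample_id),
               tolerance = 1e-12)

  # shuffling table row order leaves the multiset of distances unchanged
  tab2 <- tibble::as_tibble(sim$table)[sample(nrow(sim$table)), ]
  recs2 <- donor_outcome_distances(feature_table(tab2), sim$meta, metric = "jsd")
  key <- function(d) d[order(d$donor_sample_id, d$mixture_sample_id), ]
  expect_equal(key(recs2)$distance, key(recs)$distance, tolerance = 1e-12)
})

test_that("mixtures identical to donor A give zero distances to A and dominance of A", {
  fx <- identity_fixture(n_don = 3, n_mix = 3)
  recs <- donor_outcome_distances(fx$table, fx$meta, metric = "jsd")
  expect_true(all(recs$distance[recs$donor_label == "A"] == 0))
  expect_true(all(recs$distance[recs$donor_label == "B"] > 0))
})

test_that("missing donor replicates in a stratum raise an itemized error", {
  fx <- identity_fixture()
  meta_missing <- fx$meta[!(fx$meta$role == "donor" & fx$meta$soil_label == "B"), ]
  tab <- feature_table(tibble::as_tibble(fx$table)[
    tibble::as_tibble(fx$table)$sample_id %in% meta_missing$sample_id, ])
  expect_error(donor_outcome_distances(tab, meta_missing, metric = "jsd"),
               "no donor 'B'")
  expect_error(donor_outcome_distances(fx$table, fx$meta[-1, ], metric = "jsd"),
               "without metadata")
})

test_that("dominance test separates distinct distance distributions and is label-symmetric", {
  base <- tibble::tibble(
    treatment = "AxB", dilution = 1e-1, time_days = 1, metric = "jsd",
    donor_replicate = as.character(rep(1:6, each = 6)),
    mixture_replicate = as.character(rep(1:6, 6)))
  set.seed(61)
  recs <- dplyr::bind_rows(
    dplyr::mutate(base, donor_label = "A", distance = 0.1 + runif(36, 0, 0.003)),
    dplyr::mutate(base, donor_label = "B", distance = 0.5 + runif(36, 0, 0.003)))
  dom <- dominance_test(recs)
  expect_equal(dom$dominant, "A")
  expect_lt(dom$p_value, 0.001)
  expect_equal(dom$stars, "****")

  # swapping donor labels swaps the dominant label, p unchanged
  swapped <- dplyr::mutate(recs, donor_label = ifelse(donor_label == "A", "B", "A"))
  dom2 <- dominance_test(swapped)
  expect_equal(dom2$dominant, "B")
  expect_equal(dom2$p_value, dom$p_value)

  # same distribution for both donors: typically no dominance
  set.seed(62)
  null_recs <- dplyr::bind_rows(
    dplyr::mutate(base, donor_label = "A", distance = rlnorm(36, -1, 0.2)),
    dplyr::mutate(base, donor_label = "B", distance = rlnorm(36, -1, 0.2)))
  expect_true(dominance_test(null_recs)$dominant %in% c("none", "A", "B"))

  # a stratum missing one donor errors
  expect_error(dominance_test(dplyr::filter(recs, donor_label == "A")),
               "both")
})

test_that("dominance calls 'none' at ~1 - alpha when distance samples are independent", {
  set.seed(71)
  calls <- vapply(1:300, function(i) {
    base <- tibble::tibble(
      treatment = "AxB", dilution = 1e-1, time_days = 1, metric = "jsd",
      donor_replicate = as.character(rep(1:6, each = 6)),
      mixture_replicate = as.character(rep(1:6, 6)))
    recs <- dplyr::bind_rows(
      dplyr::mutate(base, donor_label = "A", distance = rlnorm(36, -1, 0.25)),
      dplyr::mutate(base, donor_label = "B", distance = rlnorm(36, -1, 0.25)))
    dominance_test(recs)$dominant == "none"
  }, logical(1))
  expect_gt(mean(calls), 0.95 - 2.576 * sqrt(0.05 * 0.95 / 300))
  expect_lt(mean(calls), 0.95 + 2.576 * sqrt(0.05 * 0.95 / 300))
})

test_that("contribution trends recover planted lines and stay flat under noise", {
  grid <- tidyr::expand_grid(t = c(1, 5, 15, 30), dr = 1:3, mr = 1:3)
  planted <- tibble::tibble(
    treatment = "AxB", dilution = 1e-1, time_days = grid$t,
    donor_label = "A", metric = "jsd",
    donor_replicate = as.character(grid$dr),
    mixture_replicate = as.character(grid$mr),
    distance = 0.4 - 0.01 * grid$t)
  tr <- contribution_trend(planted)
  expect_equal(tr$slope, -0.01, tolerance = 1e-12)
  expect_equal(tr$direction, "increasing_contribution")

  set.seed(83)
  flat_rate <- mean(vapply(1:200, function(i) {
    noisy <- dplyr::mutate(planted, distance = 0.4 + rnorm(nrow(planted), 0, 0.05))
    contribution_trend(noisy)$direction == "flat"
  }, logical(1)))
  expect_gt(flat_rate, 0.95 - 2.576 * sqrt(0.05 * 0.95 / 200))

  expect_error(contribution_trend(dplyr::filter(planted, time_days < 10)),
               ">= 3 distinct time points")
})

test_that("structure-function coupling joins on the replicate-pair key", {
  cfg <- scenario_config(n_features = 40, sequencing_depth = 1000,
                         n_donor_reps = 3, n_mix_reps = 3, seed = 301)
  sim <- simulate_experiment(cfg)
  s <- donor_outcome_distances(sim$table, sim$meta, metric = "jsd")

  # functional profile = structural profile -> rho = 1
  res <- structure_function_coupling(s, s)
  expect_equal(res$rho, 1)
  expect_equal(res$n_pairs, nrow(s))

  # rank reversal -> rho = -1
  f_rev <- dplyr::mutate(s, distance = max(distance) - distance)
  expect_equal(structure_function_coupling(s, f_rev)$rho, -1)

  # fewer functional replicates: unmatched records dropped and counted
  f_sub <- dplyr::filter(s, mixture_replicate %in% c("1", "2"))
  res_sub <- structure_function_coupling(s, f_sub)
  expect_equal(res_sub$n_pairs, nrow(f_sub))
  expect_equal(res_sub$n_dropped_struct, nrow(s) - nrow(f_sub))

  # independent functional distances: mostly non-significant
  set.seed(91)
  rate <- mean(vapply(1:200, function(i) {
    f_ind <- dplyr::mutate(s, distance = runif(nrow(s)))
    structure_function_coupling(s, f_ind)$p_value > 0.05
  }, logical(1)))
  expect_gt(rate, 0.95 - 2.576 * sqrt(0.05 * 0.95 / 200))

  # per-group output keeps the grouping columns
  by_res <- structure_function_coupling(s, s, by = c("treatment", "donor_label"))
  expect_equal(nrow(by_res), 2)
  expect_true(all(by_res$rho == 1))
})
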