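test_that("feature tables parse from TSV, normalize orientation, and round-trip", {
  m <- matrix(c(5, 0, 3, 2, 7, 1, 0, 4, 9, 2, 2, 6), 3, 4,
              dimnames = list(paste0("s", 1:3), paste0("asv", 1:4)))
  meta <- make_meta(n_don = 1, n_mix = 1)
  meta$sample_id <- paste0("s", 1:3)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::as_tibble(m, rownames = "sample_id"), tsv)
  ft <- read_feature_table(tsv, orientation_hint = "samples_as_rows")
  expect_s3_class(ft, "coalescr_ft")
  expect_equal(sample_ids(ft), paste0("s", 1:3))
  expect_equal(feature_ids(ft), paste0("asv", 1:4))

  # transposed file resolves identically under auto orientation
  tsv_t <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::as_tibble(t(m), rownames = "feature_id"), tsv_t)
  ft_t <- read_feature_table(tsv_t, orientation_hint = "auto", metadata = meta)
  expect_equal(tibble::as_tibble(ft_t), tibble::as_tibble(ft))

  # write/read round-trip is lossless
  out <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft, out)
  back <- read_feature_table(out, orientation_hint = "samples_as_rows")
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(ft))

  # unresolvable auto orientation errors
  expect_error(read_feature_table(tsv, orientation_hint = "auto"),
               "orientation")
})

test_that("id and value validation errors name the offender", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("dup", "dup"), c("f1", "f2")))
  expect_error(feature_table(m), "dup")
  m2 <- matrix(c(1, -2, 3, 4), 2, 2,
               dimnames = list(c("a", "b"), c("f1", "f2")))
  expect_error(feature_table(m2), "Negative")
  expect_silent(feature_table(m2, kind = "abiotic"))
  bad_meta <- make_meta()
  bad_meta$time_days <- NULL
  expect_error(validate_sample_metadata(bad_meta), "time_days")
  expect_error(validate_sample_metadata(
    dplyr::mutate(make_meta(), treatment = ifelse(role == "mixture", "AxA", treatment))),
    "distinct")
})

test_that("BIOM 1.0 JSON tables (dense and sparse) load transposed to samples x features", {
  obs <- list(list(id = "asv1"), list(id = "asv2"))
  cols <- list(list(id = "s1"), list(id = "s2"), list(id = "s3"))
  dense <- list(rows = obs, columns = cols, matrix_type = "dense",
                data = list(list(1, 2, 3), list(4, 5, 6)))
  sparse <- list(rows = obs, columns = cols, matrix_type = "sparse",
                 data = list(list(0, 0, 1), list(0, 1, 2), list(0, 2, 3),
                             list(1, 0, 4), list(1, 1, 5), list(1, 2, 6)))
  for (payload in list(dense, sparse)) {
    f <- withr::local_tempfile(fileext = ".biom")
    jsonlite::write_json(payload, f, auto_unbox = TRUE)
    ft <- read_feature_table(f, format_hint = "biom")
    expect_equal(sample_ids(ft), c("s1", "s2", "s3"))
    expect_equal(unname(as.matrix(tibble::as_tibble(ft)[-1])),
                 matrix(c(1, 2, 3, 4, 5, 6), 3, 2))
  }
})

test_that("abiotic ingestion rejects rows with missing values, itemized", {
  ab <- tibble::tibble(sample_id = c("a", "b"), pH = c(5, NA), OM = c(1, 2))
  err <- expect_error(validate_abiotic_table(ab), "missing")
  expect_match(conditionMessage(err), "b")
  expect_match(conditionMessage(err), "pH")
})

test_that("permuted rarefaction hits hypergeometric expectations and depth", {
  # total exactly at depth: returned unchanged for any n_perm
  ft <- make_ft(rbind(c(6, 3, 1), c(40, 50, 20)))
  out <- rarefy_permuted(ft, depth = 10, n_perm = 5, seed = 1)
  expect_equal(unname(as.matrix(tibble::as_tibble(out)[-1])[1, ]), c(6, 3, 1))

  # single-feature support: all reads land on it
  ft2 <- make_ft(rbind(c(100, 0, 0)))
  out2 <- rarefy_permuted(ft2, depth = 10, n_perm = 3, seed = 1)
  expect_equal(unname(as.matrix(tibble::as_tibble(out2)[-1])[1, ]), c(10, 0, 0))

  # (50, 50) at depth 10: per-feature mean over 1000 permutations is within
  # 3 hypergeometric standard errors of 5, so the rounded mean is exactly 5
  ft3 <- make_ft(rbind(c(50, 50)))
  out3 <- rarefy_permuted(ft3, depth = 10, n_perm = 1000, seed = 42)
  expect_equal(unname(as.matrix(tibble::as_tibble(out3)[-1])[1, ]), c(5, 5))

  # row sums within rounding slack of depth; exact at n_perm = 1
  set.seed(7)
  big <- make_ft(matrix(rpois(5 * 20, 30), 5, 20))
  r1 <- rarefy_permuted(big, depth = 100, n_perm = 1, seed = 3)
  expect_true(all(rowSums(as.matrix(tibble::as_tibble(r1)[-1])) == 100))
  r2 <- rarefy_permuted(big, depth = 100, n_perm = 25, seed = 3)
  expect_true(all(abs(rowSums(as.matrix(tibble::as_tibble(r2)[-1])) - 100) <= 10))

  # deterministic given seed; drops and reports shallow samples
  expect_equal(rarefy_permuted(big, depth = 100, n_perm = 10, seed = 9),
               rarefy_permuted(big, depth = 100, n_perm = 10, seed = 9))
  shallow <- make_ft(rbind(a = c(200, 100), b = c(3, 2)))
  expect_warning(res <- rarefy_permuted(shallow, depth = 50, n_perm = 2, seed = 1),
                 "b")
  expect_equal(sample_ids(res), "a")
  expect_error(rarefy_permuted(make_ft(rbind(c(1.5, 2))), depth = 1, seed = 1),
               "integer")
})

test_that("Biolog normalization subtracts water and Day-0 color, clamps at zero", {
  lay <- ecoplate_layout()
  # minimal custom layout: one substrate in triplicate + one water well
  wm <- tibble::tibble(well = c("A2", "A3", "A4"), substrate = "glucose")
  raw <- tibble::tibble(
    plate_id = "p1",
    well = rep(c("A1", "A2", "A3", "A4"), 2),
    time_h = rep(c(0, 168), each = 4),
    od = c(0.05, 0.05, 0.05, 0.05,   # Day 0: all equal to water
           0.1, 0.6, 0.7, 0.8)        # endpoint: water 0.1, wells 0.6/0.7/0.8
  )
  ft <- biolog_normalize(raw, wm, water_wells = "A1")
  expect_equal(ft_kind(ft), "metabolic")
  expect_equal(unname(as.matrix(tibble::as_tibble(ft)[-1])[1, "glucose"]), 0.6)

  # all wells equal to water at both readings -> 0
  raw0 <- dplyr::mutate(raw, od = 0.2)
  ft0 <- biolog_normalize(raw0, wm, water_wells = "A1")
  expect_equal(unname(as.matrix(tibble::as_tibble(ft0)[-1])[1, ]), 0)

  # endpoint below water clamps to 0
  raw_neg <- raw
  raw_neg$od[raw_neg$time_h == 168 & raw_neg$well != "A1"] <- 0.01
  ftn <- biolog_normalize(raw_neg, wm, water_wells = "A1")
  expect_equal(unname(as.matrix(tibble::as_tibble(ftn)[-1])[1, ]), 0)

  # invariant to well ordering within the replicate set
  ft_shuf <- biolog_normalize(raw[sample(nrow(raw)), ], wm[3:1, ], water_wells = "A1")
  expect_equal(tibble::as_tibble(ft_shuf), tibble::as_tibble(ft))

  # missing Day-0 reading errors
  expect_error(biolog_normalize(raw[raw$time_h != 0, ], wm, "A1"), "Day-0")

  # full EcoPlate layout: 31 substrates, 93 substrate wells, 3 water wells
  expect_equal(length(unique(lay$well_map$substrate)), 31)
  expect_equal(nrow(lay$well_map), 93)
  expect_equal(length(lay$water_wells), 3)
})
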