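#' Construct a feature table
#'
#' A feature table holds nonnegative measurements for a set of samples over a
#' set of features (ASVs, carbon substrates, enzymes, or abiotic variables
#' treated as features). It is stored in canonical samples-by-features
#' orientation as a tibble whose first column is `sample_id` and whose
#' remaining columns are numeric feature columns.
#'
#' @param x A data frame (first column `sample_id`, or row names used as
#'   sample ids) or a numeric matrix with row names as sample ids.
#' @param kind One of `"taxonomic"`, `"metabolic"`, `"enzymatic"`,
#'   `"abiotic"`. Values must be nonnegative for all kinds except
#'   `"abiotic"`.
#' @return A tibble of class `coalescr_ft`.
#' @export
#' @examples
#' m <- matrix(rpois(12, 20), 3, 4,
#'             dimnames = list(paste0("s", 1:3), paste0("asv", 1:4)))
#' feature_table(m, kind = "taxonomic")
feature_table <- function(x, kind = c("taxonomic", "metabolic", "enzymatic", "abiotic")) {
  kind <- match.arg(kind)
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort("Matrix input needs row names as sample ids.")
    x <- tibble::as_tibble(x, rownames = "sample_id")
  }
  x <- tibble::as_tibble(x)
  if (!"sample_id" %in% names(x)) {
    abort("Input must have a `sample_id` column (or row names).")
  }
  x <- dplyr::relocate(x, "sample_id")
  x$sample_id <- as.character(x$sample_id)
  feats <- setdiff(names(x), "sample_id")
  if (length(feats) == 0L) abort("Feature table has no feature columns.")
  if (!all(vapply(x[feats], is.numeric, logical(1)))) {
    abort("All feature columns must be numeric.")
  }
  out <- structure(x, class = c("coalescr_ft", class(tibble::tibble())))
  attr(out, "kind") <- kind
  validate_feature_table(out)
}

#' @rdname feature_table
#' @param table A `coalescr_ft` object.
#' @export
validate_feature_table <- function(table) {
  sid <- table$sample_id
  if (anyDuplicated(sid)) {
    abort(sprintf("Duplicated sample id(s): %s",
                  paste(unique(sid[duplicated(sid)]), collapse = ", ")))
  }
  fid <- feature_ids(table)
  if (anyDuplicated(fid)) {
    abort(sprintf("Duplicated feature id(s): %s",
                  paste(unique(fid[duplicated(fid)]), collapse = ", ")))
  }
  vals <- ft_matrix(table)
  if (anyNA(vals)) abort("Feature table contains missing values.")
  if (ft_kind(table) != "abiotic" && any(vals < 0)) {
    abort(sprintf("Negative values are not allowed for kind '%s'.", ft_kind(table)))
  }
  table
}

#' @rdname feature_table
#' @export
ft_kind <- function(table) attr(table, "kind") %||% "taxonomic"

#' @rdname feature_table
#' @export
sample_ids <- function(table) table$sample_id

#' @rdname feature_table
#' @export
feature_ids <- function(table) setdiff(names(table), "sample_id")

# samples x features numeric matrix with sample ids as row names
ft_matrix <- function(table) {
  m <- as.matrix(table[feature_ids(table)])
  rownames(m) <- table$sample_id
  storage.mode(m) <- "double"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a feature table from delimited text or BIOM
#'
#' Reads a samples-by-features (or features-by-samples) table and normalizes
#' it to the canonical samples-by-features orientation. Orientation can be
#' forced, or resolved automatically by matching ids against sample metadata.
#'
#' @param path Path to a TSV/CSV file (first column = row labels, header =
#'   column labels) or a BIOM JSON file.
#' @param kind Passed to [feature_table()].
#' @param format_hint `"auto"` (by extension), `"tsv"`, `"csv"` or `"biom"`.
#' @param orientation_hint `"auto"`, `"samples_as_rows"` or
#'   `"features_as_rows"`. Under `"auto"`, row and column labels are matched
#'   against `metadata$sample_id`; the axis matching the metadata becomes the
#'   sample axis.
#' @param metadata Optional sample metadata (see [read_sample_metadata()]),
#'   required to resolve `"auto"` orientation when neither axis is obvious.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path,
                               kind = "taxonomic",
                               format_hint = c("auto", "tsv", "csv", "biom"),
                               orientation_hint = c("auto", "samples_as_rows", "features_as_rows"),
                               metadata = NULL) {
  format_hint <- match.arg(format_hint)
  orientation_hint <- match.arg(orientation_hint)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format_hint == "auto") {
    ext <- tolower(tools::file_ext(path))
    format_hint <- switch(ext, csv = "csv", biom = "biom", json = "biom", "tsv")
  }
  if (format_hint == "biom") {
    # BIOM fixes the orientation (rows = observations); already canonicalized
    return(feature_table(read_biom_json(path), kind = kind))
  } else {
    delim <- if (format_hint == "csv") "," else "\t"
    df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
    rlab <- as.character(df[[1]])
    m <- as.matrix(df[-1])
    if (!is.numeric(m)) abort(sprintf("Non-numeric values in %s", path))
    rownames(m) <- rlab
  }
  m <- orient_matrix(m, orientation_hint, metadata, path)
  feature_table(m, kind = kind)
}

# BIOM 1.0 (JSON) reader: dense or sparse matrix_type, rows = observations.
read_biom_json <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(b$rows) || is.null(b$columns)) {
    abort(sprintf("Not a BIOM 1.0 JSON file: %s", path))
  }
  obs <- vapply(b$rows, function(r) r$id, character(1))
  samp <- vapply(b$columns, function(r) r$id, character(1))
  m <- matrix(0, length(obs), length(samp), dimnames = list(obs, samp))
  if (identical(b$matrix_type, "dense")) {
    for (i in seq_along(b$data)) m[i, ] <- unlist(b$data[[i]])
  } else {
    for (trip in b$data) {
      m[trip[[1]] + 1L, trip[[2]] + 1L] <- trip[[3]]
    }
  }
  # BIOM rows are observations (features); transpose to samples x features
  t(m)
}

orient_matrix <- function(m, orientation_hint, metadata, path) {
  if (orientation_hint == "samples_as_rows") return(m)
  if (orientation_hint == "features_as_rows") return(t(m))
  ids <- if (!is.null(metadata)) unique(as.character(metadata$sample_id)) else character()
  row_hits <- mean(rownames(m) %in% ids)
  col_hits <- mean(colnames(m) %in% ids)
  if (length(ids) == 0L || (row_hits == 0 && col_hits == 0)) {
    abort(sprintf(paste0(
      "Cannot resolve orientation of %s automatically: no row or column ",
      "labels match the metadata sample ids. Pass `orientation_hint` or ",
      "`metadata`."), path))
  }
  if (row_hits == col_hits) {
    abort(sprintf("Orientation of %s is ambiguous: both axes match metadata equally.", path))
  }
  if (col_hits > row_hits) t(m) else m
}

#' @rdname read_feature_table
#' @param table A [feature_table()] to write.
#' @export
write_feature_table <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(path)
}

metadata_required_cols <- c("sample_id", "role", "soil_label", "treatment",
                            "dilution", "time_days", "replicate")

#' Read and validate sample metadata
#'
#' Metadata describes each sample's role in the coalescence design: whether it
#' is a `donor` control microcosm or a `mixture`, which soil or soil pair it
#' carries, its biotic dilution level, sampling day, and replicate.
#'
#' @param path TSV file with columns `sample_id`, `role`, `soil_label`,
#'   `treatment`, `dilution`, `time_days`, `replicate`. For mixtures,
#'   `treatment` names the two donor soils joined by `x` (e.g. `AxB`); donor
#'   rows carry their own `soil_label` (their `treatment` may be empty).
#' @return A validated tibble.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_metadata(meta)
}

#' @rdname read_sample_metadata
#' @param meta A metadata data frame to validate.
#' @export
validate_sample_metadata <- function(meta) {
  meta <- tibble::as_tibble(meta)
  missing_cols <- setdiff(metadata_required_cols, names(meta))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Metadata is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) {
    abort(sprintf("Duplicated sample id(s) in metadata: %s",
                  paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
                        collapse = ", ")))
  }
  bad_role <- setdiff(unique(meta$role), c("donor", "mixture"))
  if (length(bad_role) > 0L) {
    abort(sprintf("`role` must be 'donor' or 'mixture'; found: %s",
                  paste(bad_role, collapse = ", ")))
  }
  if (any(meta$time_days < 0, na.rm = TRUE)) abort("`time_days` must be nonnegative.")
  mix <- meta[meta$role == "mixture", ]
  if (nrow(mix) > 0L) {
    parts <- strsplit(as.character(mix$treatment), "x", fixed = TRUE)
    bad <- vapply(parts, function(p) length(p) != 2L || p[1] == p[2], logical(1))
    if (any(bad)) {
      abort(sprintf(
        "Mixture treatment(s) must name two distinct donors as '<a>x<b>': %s",
        paste(unique(mix$treatment[bad]), collapse = ", ")))
    }
  }
  meta
}

# Split "AxB" into c("A", "B")
treatment_donors <- function(treatment) {
  strsplit(as.character(treatment), "x", fixed = TRUE)[[1]]
}

#' Read an abiotic (physicochemical) properties table
#'
#' One row per sample, one numeric column per variable (pH, organic matter,
#' nitrogen pools, texture fractions, ...). Rows containing missing values
#' are rejected with an itemized error, since downstream distances and deltas
#' require complete cases.
#'
#' @param path TSV/CSV file; first column `sample_id`.
#' @param format_hint `"auto"`, `"tsv"` or `"csv"`.
#' @return A tibble with `sample_id` plus numeric variable columns.
#' @export
read_abiotic_table <- function(path, format_hint = c("auto", "tsv", "csv")) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format_hint == "auto") {
    format_hint <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "tsv"
  }
  delim <- if (format_hint == "csv") "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  names(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  validate_abiotic_table(df)
}

#' @rdname read_abiotic_table
#' @param abiotic An abiotic data frame to validate.
#' @export
validate_abiotic_table <- function(abiotic) {
  abiotic <- tibble::as_tibble(abiotic)
  if (!"sample_id" %in% names(abiotic)) abort("Abiotic table needs a `sample_id` column.")
  vars <- setdiff(names(abiotic), "sample_id")
  if (length(vars) == 0L) abort("Abiotic table has no variable columns.")
  if (!all(vapply(abiotic[vars], is.numeric, logical(1)))) {
    abort("All abiotic variable columns must be numeric.")
  }
  cc <- complete.cases(abiotic[vars])
  if (!all(cc)) {
    bad <- abiotic$sample_id[!cc]
    items <- vapply(which(!cc), function(i) {
      miss <- vars[is.na(unlist(abiotic[i, vars]))]
      sprintf("%s (%s)", abiotic$sample_id[i], paste(miss, collapse = ", "))
    }, character(1))
    abort(sprintf("Abiotic rows with missing values: %s",
                  paste(items, collapse = "; ")))
  }
  if (anyDuplicated(abiotic$sample_id)) {
    abort(sprintf("Duplicated sample id(s) in abiotic table: %s",
                  paste(unique(abiotic$sample_id[duplicated(abiotic$sample_id)]),
                        collapse = ", ")))
  }
  abiotic
}
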