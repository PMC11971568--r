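#' Enumerate the factorial microcosm design
#'
#' Builds the sample layout of a pairwise soil-coalescence experiment: every
#' soil pair becomes a mixture unit and every soil a donor control unit, each
#' crossed with the biotic dilution levels, sampling days and replicates. A
#' subset of replicates per unit is flagged for the Biolog carbon-metabolism
#' assay.
#'
#' @param soils Donor soil labels (default A, B, C).
#' @param dilutions Biotic dilution levels (default 1e-1, 1e-3, 1e-5).
#' @param times Sampling days (default 1, 5, 15, 30).
#' @param n_replicates Replicates per unit (default 6).
#' @param biolog_replicates Replicates per unit assayed on EcoPlates
#'   (default 4).
#' @return A tibble with one row per sample: `unit` (soil or pair label),
#'   `role`, `dilution`, `time_days`, `replicate`, `biolog`.
#' @export
#' @examples
#' d <- experiment_design()
#' design_totals(d)  # 432 samples, 288 Biolog plates
experiment_design <- function(soils = c("A", "B", "C"),
                              dilutions = c(1e-1, 1e-3, 1e-5),
                              times = c(1, 5, 15, 30),
                              n_replicates = 6,
                              biolog_replicates = 4) {
  if (length(soils) < 2) abort("Need at least two soils.")
  pairs <- utils::combn(soils, 2, FUN = function(p) paste(p, collapse = "x"))
  units <- dplyr::bind_rows(
    tibble(unit = pairs, role = "mixture"),
    tibble(unit = soils, role = "donor")
  )
  tidyr::expand_grid(units,
                     dilution = dilutions,
                     time_days = times,
                     replicate = seq_len(n_replicates)) %>%
    dplyr::mutate(biolog = .data$replicate <= biolog_replicates)
}

#' @rdname experiment_design
#' @param design Output of [experiment_design()].
#' @export
design_totals <- function(design) {
  tibble(n_samples = nrow(design),
         n_biolog_plates = sum(design$biolog))
}
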