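#' Normalize Biolog EcoPlate OD readings into a substrate-utilization profile
#'
#' EcoPlates carry 31 carbon substrates in triplicate plus water-only control
#' wells; color development (OD590) reflects substrate utilization. For each
#' substrate, the normalized value is the mean over its replicate wells of
#'
#' \deqn{(OD_{end} - OD^{water}_{end}) - (OD_{0} - OD^{water}_{0})}
#'
#' i.e. the endpoint reading referenced to the water control, minus the same
#' quantity at the Day-0 reading (removing the color effect of soil particles).
#' Negative values are clamped to zero so the profiles remain valid inputs to
#' probabilistic distances such as the Jensen-Shannon divergence.
#'
#' @param raw Long tibble of plate readings with columns `plate_id`, `well`,
#'   `time_h`, `od`. Must contain a reading at `time_h = 0` (Day 0) and at
#'   `endpoint_hours` for every well.
#' @param well_map Tibble mapping `well` to `substrate`; wells listed in
#'   `water_wells` need not appear.
#' @param water_wells Character vector of water-only control wells.
#' @param endpoint_hours Reading used as the endpoint; default 168 (the final
#'   reading of a 7-day incubation). Any recorded time may be selected.
#' @return A [feature_table()] of kind `"metabolic"`: one row per plate
#'   (`sample_id = plate_id`), one column per substrate.
#' @export
biolog_normalize <- function(raw, well_map, water_wells, endpoint_hours = 168) {
  raw <- tibble::as_tibble(raw)
  need <- setdiff(c("plate_id", "well", "time_h", "od"), names(raw))
  if (length(need) > 0L) {
    abort(sprintf("`raw` is missing column(s): %s", paste(need, collapse = ", ")))
  }
  well_map <- tibble::as_tibble(well_map)
  if (!all(c("well", "substrate") %in% names(well_map))) {
    abort("`well_map` needs columns `well` and `substrate`.")
  }
  if (length(water_wells) == 0L) abort("`water_wells` must be nonempty.")
  well_map <- well_map[!well_map$well %in% water_wells, ]
  empty <- well_map$substrate[!nzchar(well_map$substrate) | is.na(well_map$substrate)]
  if (length(empty) > 0L) abort("`well_map` contains wells with no substrate.")
  if (nrow(well_map) == 0L) abort("No substrate wells left after removing water wells.")

  get_reading <- function(t, label) {
    r <- raw[raw$time_h == t, c("plate_id", "well", "od")]
    if (nrow(r) == 0L) abort(sprintf("No %s reading (time_h = %s) found.", label, t))
    r
  }
  end <- get_reading(endpoint_hours, "endpoint")
  day0 <- get_reading(0, "Day-0")

  per_plate <- function(pid) {
    e <- end[end$plate_id == pid, ]
    z <- day0[day0$plate_id == pid, ]
    if (nrow(z) == 0L) abort(sprintf("Missing Day-0 reading for plate %s.", pid))
    e_od <- setNames(e$od, e$well)
    z_od <- setNames(z$od, z$well)
    if (!all(water_wells %in% names(e_od)) || !all(water_wells %in% names(z_od))) {
      abort(sprintf("Plate %s is missing water-well reading(s).", pid))
    }
    w_end <- mean(e_od[water_wells])
    w_0 <- mean(z_od[water_wells])
    vals <- vapply(split(well_map$well, well_map$substrate), function(wells) {
      if (!all(wells %in% names(e_od)) || !all(wells %in% names(z_od))) {
        abort(sprintf("Plate %s is missing reading(s) for well(s) %s.",
                      pid, paste(setdiff(wells, names(e_od)), collapse = ", ")))
      }
      mean((e_od[wells] - w_end) - (z_od[wells] - w_0))
    }, numeric(1))
    pmax(vals, 0)
  }

  plates <- unique(end$plate_id)
  m <- do.call(rbind, lapply(plates, per_plate))
  rownames(m) <- plates
  feature_table(m, kind = "metabolic")
}

#' Standard EcoPlate well map
#'
#' The 96-well EcoPlate layout holds 31 substrates plus a water control, each
#' in triplicate (columns 1-4, 5-8, 9-12). This helper builds a generic map
#' with substrates labelled `S01`-`S31` and water in wells A1, A5, A9;
#' real plate layouts can be supplied to [biolog_normalize()] directly.
#'
#' @return A list with elements `well_map` (tibble `well`, `substrate`) and
#'   `water_wells` (character).
#' @export
ecoplate_layout <- function() {
  rows <- LETTERS[1:8]
  block_cols <- list(1:4, 5:8, 9:12)
  wells <- unlist(lapply(block_cols, function(cols) {
    as.vector(t(outer(rows, cols, paste0)))
  }))
  # within each 32-well block: first well is water, the rest are S01..S31
  per_block <- c("water", sprintf("S%02d", 1:31))
  map <- tibble(well = wells, substrate = rep(per_block, times = 3))
  list(well_map = map[map$substrate != "water", ],
       water_wells = map$well[map$substrate == "water"])
}
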