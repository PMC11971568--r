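# Framework core: donor-to-outcome distance distributions per stratum,
# dominance testing, temporal trends, and structure-function coupling.

contribution_keys <- c("treatment", "dilution", "time_days")

#' All donor-to-outcome distances per stratum
#'
#' For every (treatment, dilution, time) stratum, computes the full
#' cross-product of distances from each donor replicate (the single-soil
#' control microcosm) to each mixture replicate, for both donors named by the
#' treatment. By default the donor reference at time t is the donor control
#' sampled at the same time t; `donor_reference = "baseline"` uses the
#' earliest sampled donor controls instead.
#'
#' @param table A [feature_table()] covering donors and mixtures.
#' @param meta Sample metadata (see [read_sample_metadata()]).
#' @param metric Distance metric (see [pairwise_distances()]).
#' @param treatments,dilutions,times Optional filters; default all strata
#'   present among the mixtures.
#' @param donor_reference `"same_time"` (default) or `"baseline"`.
#' @param ... Metric options (`variant`, `ground_distance`).
#' @return A tibble of contribution records, one row per donor replicate x
#'   mixture replicate pair per stratum: `treatment`, `dilution`,
#'   `time_days`, `donor_label`, `donor_replicate`, `mixture_replicate`,
#'   `donor_sample_id`, `mixture_sample_id`, `metric`, `distance`.
#' @export
donor_outcome_distances <- function(table, meta,
                                    metric = c("jsd", "bray_curtis", "euclidean", "cosine", "emd"),
                                    treatments = NULL, dilutions = NULL, times = NULL,
                                    donor_reference = c("same_time", "baseline"),
                                    ...) {
  metric <- match.arg(metric)
  donor_reference <- match.arg(donor_reference)
  meta <- validate_sample_metadata(meta)
  ids <- sample_ids(table)
  missing_meta <- setdiff(ids, meta$sample_id)
  if (length(missing_meta) > 0L) {
    abort(sprintf("Sample(s) in the table without metadata: %s",
                  paste(head(missing_meta, 10), collapse = ", ")))
  }
  meta <- meta[meta$sample_id %in% ids, ]
  prof <- prepare_metric_input(ft_matrix(table), metric, ft_kind(table))
  fun <- metric_registry()[[metric]]

  mix <- meta[meta$role == "mixture", ]
  if (!is.null(treatments)) mix <- mix[mix$treatment %in% treatments, ]
  if (!is.null(dilutions)) mix <- mix[mix$dilution %in% dilutions, ]
  if (!is.null(times)) mix <- mix[mix$time_days %in% times, ]
  if (nrow(mix) == 0L) abort("No mixture samples match the requested strata.")

  strata <- dplyr::distinct(mix[contribution_keys])
  problems <- character()
  out <- purrr::pmap(strata, function(treatment, dilution, time_days) {
    mix_rows <- mix[mix$treatment == treatment & mix$dilution == dilution &
                      mix$time_days == time_days, ]
    donors <- treatment_donors(treatment)
    donor_time <- if (donor_reference == "same_time") time_days else {
      dt <- meta$time_days[meta$role == "donor" & meta$dilution == dilution]
      if (length(dt) == 0L) time_days else min(dt)
    }
    recs <- purrr::map(donors, function(dl) {
      don_rows <- meta[meta$role == "donor" & meta$soil_label == dl &
                         meta$dilution == dilution & meta$time_days == donor_time, ]
      if (nrow(don_rows) == 0L) {
        problems <<- c(problems, sprintf(
          "no donor '%s' replicates for treatment %s, dilution %s, day %s",
          dl, treatment, format(dilution), format(donor_time)))
        return(NULL)
      }
      pairs <- tidyr::expand_grid(di = seq_len(nrow(don_rows)),
                                  mi = seq_len(nrow(mix_rows)))
      tibble(
        treatment = treatment, dilution = dilution, time_days = time_days,
        donor_label = dl,
        donor_replicate = as.character(don_rows$replicate[pairs$di]),
        mixture_replicate = as.character(mix_rows$replicate[pairs$mi]),
        donor_sample_id = don_rows$sample_id[pairs$di],
        mixture_sample_id = mix_rows$sample_id[pairs$mi],
        metric = metric,
        distance = purrr::map2_dbl(don_rows$sample_id[pairs$di],
                                   mix_rows$sample_id[pairs$mi],
                                   function(a, b) fun(prof[a, ], prof[b, ], ...))
      )
    })
    dplyr::bind_rows(recs)
  })
  if (length(problems) > 0L) {
    abort(paste0("Incomplete strata:\n  ", paste(problems, collapse = "\n  ")))
  }
  res <- dplyr::bind_rows(out)
  attr(res, "metric") <- metric
  res
}

#' Per-stratum donor dominance test
#'
#' Within each (treatment, dilution, time, metric) stratum, compares the two
#' donors' distance distributions with [compare_distributions()] (Shapiro-Wilk
#' gate, then Welch's t or Mann-Whitney U). The dominant donor is the one with
#' the smaller mean donor-to-outcome distance when the comparison is
#' significant at `alpha`; otherwise `"none"` — the symmetric outcome expected
#' under 50:50 mixing with no differential engraftment.
#'
#' @param records Contribution records from [donor_outcome_distances()].
#' @param alpha Significance level (default 0.05).
#' @param alpha_normality Normality-gate level (default 0.05).
#' @return A tibble with one row per stratum: donor labels, mean ± sd of each
#'   donor's distances, the test taken (`method`, `statistic`, `p_value`,
#'   `stars`), and `dominant` (`donor_1` label, `donor_2` label, or
#'   `"none"`).
#' @export
dominance_test <- function(records, alpha = 0.05, alpha_normality = 0.05) {
  records <- tibble::as_tibble(records)
  grp <- c(contribution_keys, "metric")
  records %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) %>%
    dplyr::group_modify(function(df, key) {
      donors <- treatment_donors(key$treatment)
      present <- unique(df$donor_label)
      if (!setequal(present, donors)) {
        abort(sprintf(
          "Stratum %s / %s / day %s has donor(s) %s only; both %s and %s are required.",
          key$treatment, format(key$dilution), format(key$time_days),
          paste(present, collapse = ", "), donors[1], donors[2]))
      }
      d1 <- df$distance[df$donor_label == donors[1]]
      d2 <- df$distance[df$donor_label == donors[2]]
      if (length(d1) < 3 || length(d2) < 3) {
        abort(sprintf("Stratum %s / %s / day %s has < 3 records per donor.",
                      key$treatment, format(key$dilution), format(key$time_days)))
      }
      test <- compare_distributions(d1, d2, alpha = alpha,
                                    alpha_normality = alpha_normality)
      dominant <- if (test$p_value < alpha) {
        if (mean(d1) < mean(d2)) donors[1] else donors[2]
      } else "none"
      tibble(donor_1 = donors[1], donor_2 = donors[2],
             mean_dist_1 = mean(d1), sd_dist_1 = sd(d1), n_1 = length(d1),
             mean_dist_2 = mean(d2), sd_dist_2 = sd(d2), n_2 = length(d2),
             method = test$method, statistic = test$statistic,
             p_value = test$p_value, stars = significance_stars(test$p_value),
             dominant = dominant)
    }) %>%
    dplyr::ungroup()
}

#' Temporal trend of donor contribution
#'
#' Regresses donor-to-outcome distance on time within each (treatment,
#' dilution, donor, metric) group. Because smaller distances mean larger
#' contributions, a significantly negative slope is an *increasing*
#' contribution over time. By default all replicate-pair distances are pooled
#' into the regression; `mode = "means"` first averages distances per time
#' point.
#'
#' @param records Contribution records from [donor_outcome_distances()].
#' @param alpha Significance level for the slope test (default 0.05).
#' @param mode `"pairs"` (pool every replicate-pair distance) or `"means"`
#'   (one mean distance per time point).
#' @return A tibble with one row per group: `slope`, `intercept`, `p_value`,
#'   `r_squared`, `n_points`, `direction`.
#' @export
contribution_trend <- function(records, alpha = 0.05, mode = c("pairs", "means")) {
  mode <- match.arg(mode)
  records <- tibble::as_tibble(records)
  grp <- c("treatment", "dilution", "donor_label", "metric")
  records %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) %>%
    dplyr::group_modify(function(df, key) {
      if (dplyr::n_distinct(df$time_days) < 3) {
        abort(sprintf(
          "Trend for %s donor %s needs >= 3 distinct time points; got %d.",
          key$treatment, key$donor_label, dplyr::n_distinct(df$time_days)))
      }
      if (mode == "means") {
        df <- df %>%
          dplyr::group_by(.data$time_days) %>%
          dplyr::summarise(distance = mean(.data$distance), .groups = "drop")
      }
      ols_fit(df$time_days, df$distance, alpha = alpha)
    }) %>%
    dplyr::ungroup()
}

coupling_keys <- c("treatment", "dilution", "donor_label", "time_days",
                   "donor_replicate", "mixture_replicate")

#' Coupling between structural and functional donor contributions
#'
#' Inner-joins structural (e.g. ASV-based) and functional (e.g. Biolog or
#' enzyme) contribution records on the full replicate-pair key, then computes
#' the Spearman correlation between the two distance sets. Unmatched records
#' (e.g. community replicates without a functional assay) are dropped and
#' counted.
#'
#' @param struct_records,func_records Contribution records from
#'   [donor_outcome_distances()] on the structural and functional tables.
#' @param by Optional character vector of grouping columns (subset of the
#'   join key, e.g. `c("treatment", "dilution")`) to compute one correlation
#'   per group; default a single overall correlation.
#' @return A tibble with `rho`, `p_value`, `n_pairs`, plus the number of
#'   records dropped from each side (and the `by` columns, if any).
#' @export
structure_function_coupling <- function(struct_records, func_records, by = NULL) {
  s <- tibble::as_tibble(struct_records)
  f <- tibble::as_tibble(func_records)
  joined <- dplyr::inner_join(
    dplyr::select(s, dplyr::all_of(coupling_keys), struct_distance = "distance"),
    dplyr::select(f, dplyr::all_of(coupling_keys), func_distance = "distance"),
    by = coupling_keys
  )
  n_dropped_struct <- nrow(s) - nrow(joined)
  n_dropped_func <- nrow(f) - nrow(joined)
  one <- function(df) {
    if (nrow(df) < 4) {
      abort(sprintf("Coupling needs >= 4 matched pairs; got %d.", nrow(df)))
    }
    sp <- spearman(df$struct_distance, df$func_distance)
    tibble(rho = sp$rho, p_value = sp$p_value, n_pairs = sp$n)
  }
  res <- if (is.null(by)) {
    one(joined)
  } else {
    joined %>%
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) %>%
      dplyr::group_modify(~ one(.x)) %>%
      dplyr::ungroup()
  }
  res$n_dropped_struct <- n_dropped_struct
  res$n_dropped_func <- n_dropped_func
  res
}

#' Boxplot of donor contributions over time
#'
#' Mirrors the framework's standard display: per time point, side-by-side
#' boxplots of each donor's distance distribution to the outcome community
#' (smaller distance = larger contribution), faceted by treatment and
#' dilution, with significance stars from [dominance_test()] if supplied.
#'
#' @param records Contribution records.
#' @param dominance Optional output of [dominance_test()] on the same records.
#' @return A ggplot object.
#' @export
plot_contribution <- function(records, dominance = NULL) {
  records <- tibble::as_tibble(records)
  p <- ggplot2::ggplot(records,
                       ggplot2::aes(factor(.data$time_days), .data$distance,
                                    fill = .data$donor_label)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, linewidth = 0.3) +
    ggplot2::facet_grid(dilution ~ treatment, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Time (days)",
                  y = sprintf("Donor-to-outcome distance (%s)",
                              records$metric[1]),
                  fill = "Donor") +
    ggplot2::theme_minimal()
  if (!is.null(dominance)) {
    ann <- dplyr::mutate(tibble::as_tibble(dominance),
                         y = pmax(.data$mean_dist_1 + 3 * .data$sd_dist_1,
                                  .data$mean_dist_2 + 3 * .data$sd_dist_2))
    p <- p + ggplot2::geom_text(
      data = ann,
      ggplot2::aes(factor(.data$time_days), .data$y, label = .data$stars),
      inherit.aes = FALSE, size = 3)
  }
  p
}
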