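# Abiotic-driver pipeline: per-variable absolute deltas between donor and
# mixture environments paired with community dissimilarity, and
# permutation-based random-forest importance.

delta_keys <- c("treatment", "dilution", "time_days", "donor_label",
                "donor_replicate", "mixture_replicate")

#' Absolute abiotic deltas paired with community dissimilarity
#'
#' For every donor replicate x mixture replicate pair in each (treatment,
#' dilution, time) stratum, emits one record per abiotic variable with
#' `delta = |donor value - mixture value|` and the paired Bray-Curtis
#' community distance for the same pair of samples. When a sample has no row
#' of its own in the abiotic table (chemistry measured per treatment rather
#' than per sequencing replicate), the stratum-level mean of the matching
#' abiotic rows is broadcast across the community replicates; the `broadcast`
#' column records when this happened.
#'
#' @param abiotic Abiotic table (see [read_abiotic_table()]).
#' @param meta Sample metadata.
#' @param community_dm Bray-Curtis `coalescr_dist` over the community
#'   samples being paired.
#' @return A tibble with the stratum/replicate key columns plus `variable`,
#'   `delta`, `paired_bc`, `broadcast`.
#' @export
abiotic_delta <- function(abiotic, meta, community_dm) {
  abiotic <- validate_abiotic_table(abiotic)
  meta <- validate_sample_metadata(meta)
  vars <- setdiff(names(abiotic), "sample_id")
  dm_ids <- rownames(as.matrix(community_dm))

  lookup_abiotic <- function(sample_row) {
    if (sample_row$sample_id %in% abiotic$sample_id) {
      vals <- unlist(abiotic[abiotic$sample_id == sample_row$sample_id, vars])
      return(list(values = vals, broadcast = FALSE))
    }
    # broadcast: average the abiotic rows of samples sharing the stratum
    sib <- meta[meta$role == sample_row$role &
                  meta$dilution == sample_row$dilution &
                  meta$time_days == sample_row$time_days, ]
    sib <- if (sample_row$role == "donor") {
      sib[sib$soil_label == sample_row$soil_label, ]
    } else {
      sib[sib$treatment == sample_row$treatment, ]
    }
    hit <- abiotic[abiotic$sample_id %in% sib$sample_id, vars]
    if (nrow(hit) == 0L) {
      abort(sprintf("No abiotic values for sample %s (nor for its stratum).",
                    sample_row$sample_id))
    }
    list(values = colMeans(hit), broadcast = TRUE)
  }

  mix <- meta[meta$role == "mixture" & meta$sample_id %in% dm_ids, ]
  if (nrow(mix) == 0L) abort("No mixture samples shared between metadata and distance matrix.")
  strata <- dplyr::distinct(mix[contribution_keys])
  out <- purrr::pmap(strata, function(treatment, dilution, time_days) {
    mix_rows <- mix[mix$treatment == treatment & mix$dilution == dilution &
                      mix$time_days == time_days, ]
    donors <- treatment_donors(treatment)
    purrr::map(donors, function(dl) {
      don_rows <- meta[meta$role == "donor" & meta$soil_label == dl &
                         meta$dilution == dilution & meta$time_days == time_days &
                         meta$sample_id %in% dm_ids, ]
      if (nrow(don_rows) == 0L) {
        abort(sprintf("No donor '%s' replicates in the distance matrix for %s / %s / day %s.",
                      dl, treatment, format(dilution), format(time_days)))
      }
      pairs <- tidyr::expand_grid(di = seq_len(nrow(don_rows)),
                                  mi = seq_len(nrow(mix_rows)))
      purrr::map2(pairs$di, pairs$mi, function(di, mi) {
        don <- don_rows[di, ]; mx <- mix_rows[mi, ]
        av_d <- lookup_abiotic(don); av_m <- lookup_abiotic(mx)
        tibble(
          treatment = treatment, dilution = dilution, time_days = time_days,
          donor_label = dl,
          donor_replicate = as.character(don$replicate),
          mixture_replicate = as.character(mx$replicate),
          variable = vars,
          delta = unname(abs(av_d$values - av_m$values)),
          paired_bc = dist_lookup(community_dm, don$sample_id, mx$sample_id),
          broadcast = av_d$broadcast || av_m$broadcast
        )
      }) %>% dplyr::bind_rows()
    }) %>% dplyr::bind_rows()
  })
  dplyr::bind_rows(out)
}

#' Random-forest importance of abiotic deltas with permutation p-values
#'
#' Pivots the delta records wide (one observation per donor/mixture replicate
#' pair, one predictor column per abiotic variable, response = the paired
#' Bray-Curtis community distance) and fits a random-forest regression.
#' Importance is out-of-bag permutation importance: by default
#' `pct_inc_mse` is the raw mean increase in OOB MSE when the predictor is
#' permuted, expressed as a percentage of the model's OOB MSE;
#' `scale = "scaled"` reports the classic importance z-score instead (raw
#' mean divided by its standard error). Per-variable p-values come from
#' refitting the forest on a response permuted across observations
#' (`n_response_permutations` times) and computing the add-one tail
#' probability of the observed raw importance under that null.
#'
#' @param deltas Output of [abiotic_delta()] or [simulate_abiotic()].
#' @param n_trees Trees per forest (default 1000).
#' @param n_response_permutations Response permutations for the null
#'   (default 100).
#' @param seed Integer seed (required for reproducibility).
#' @param scale `"raw"` (default) or `"scaled"`.
#' @return A `coalescr_rfimp` object; `tidy()` gives the per-variable table
#'   (sorted by importance), `glance()` the model-level summary including
#'   `model_variance_explained` (percent, `100 * (1 - OOB MSE / var(y))`).
#' @export
rf_importance <- function(deltas, n_trees = 1000, n_response_permutations = 100,
                          seed = NULL, scale = c("raw", "scaled")) {
  scale <- match.arg(scale)
  deltas <- tibble::as_tibble(deltas)
  wide <- deltas %>%
    dplyr::select(dplyr::any_of(c(delta_keys, "variable", "delta", "paired_bc"))) %>%
    tidyr::pivot_wider(names_from = "variable", values_from = "delta")
  vars <- unique(deltas$variable)
  if (length(vars) < 2) abort("rf_importance() needs >= 2 predictor variables.")
  x <- as.data.frame(wide[vars])
  y <- wide$paired_bc
  if (length(y) < 20) {
    abort(sprintf("rf_importance() needs >= 20 observations; got %d.", length(y)))
  }
  if (var(y) == 0) abort("Response (paired_bc) is constant.")

  raw_imp <- function(xx, yy) {
    rf <- randomForest::randomForest(xx, yy, ntree = n_trees, importance = TRUE)
    list(imp = randomForest::importance(rf, type = 1, scale = FALSE)[, 1],
         imp_scaled = randomForest::importance(rf, type = 1, scale = TRUE)[, 1],
         mse = rf$mse[n_trees],
         rsq = rf$rsq[n_trees])
  }
  fit <- with_seed_(seed, {
    obs <- raw_imp(x, y)
    null <- matrix(NA_real_, n_response_permutations, length(vars),
                   dimnames = list(NULL, vars))
    for (b in seq_len(n_response_permutations)) {
      null[b, ] <- raw_imp(x, sample(y))$imp
    }
    list(obs = obs, null = null)
  })
  obs <- fit$obs
  p_vals <- vapply(vars, function(v) {
    (1 + sum(fit$null[, v] >= obs$imp[v])) / (1 + n_response_permutations)
  }, numeric(1))
  pct <- if (scale == "raw") 100 * obs$imp / obs$mse else obs$imp_scaled
  imp_tbl <- tibble(
    variable = vars,
    pct_inc_mse = unname(pct[vars]),
    p_value = unname(p_vals[vars]),
    stars = significance_stars(unname(p_vals[vars]))
  ) %>% dplyr::arrange(dplyr::desc(.data$pct_inc_mse))
  structure(
    list(importance = imp_tbl,
         model_variance_explained = 100 * obs$rsq,
         oob_mse = obs$mse,
         n_obs = length(y), n_trees = n_trees,
         n_response_permutations = n_response_permutations,
         scale = scale, seed = seed),
    class = "coalescr_rfimp"
  )
}

#' @export
print.coalescr_rfimp <- function(x, ...) {
  cat(sprintf("<coalescr_rfimp> %d obs, %d trees, %d response permutations\n",
              x$n_obs, x$n_trees, x$n_response_permutations))
  cat(sprintf("variance explained: %.1f%%\n", x$model_variance_explained))
  print(x$importance)
  invisible(x)
}

#' @rdname rf_importance
#' @param x,object A `coalescr_rfimp`.
#' @param ... Unused.
#' @method tidy coalescr_rfimp
#' @export
tidy.coalescr_rfimp <- function(x, ...) x$importance

#' @rdname rf_importance
#' @method glance coalescr_rfimp
#' @export
glance.coalescr_rfimp <- function(x, ...) {
  tibble(model_variance_explained = x$model_variance_explained,
         oob_mse = x$oob_mse, n_obs = x$n_obs, n_trees = x$n_trees,
         n_response_permutations = x$n_response_permutations)
}

#' Importance bar plot
#'
#' Bar plot of per-variable importance, significant drivers highlighted, with
#' the model's total variance explained in the title.
#'
#' @param imp A `coalescr_rfimp`.
#' @param alpha Highlight threshold (default 0.05).
#' @return A ggplot object.
#' @export
plot_importance <- function(imp, alpha = 0.05) {
  df <- dplyr::mutate(imp$importance,
                      significant = .data$p_value < alpha,
                      variable = factor(.data$variable,
                                        levels = rev(.data$variable)))
  ggplot2::ggplot(df, ggplot2::aes(.data$pct_inc_mse, .data$variable,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey60")) +
    ggplot2::labs(x = "% increase in MSE", y = NULL,
                  title = sprintf("Abiotic drivers (%.1f%% variance explained)",
                                  imp$model_variance_explained)) +
    ggplot2::theme_minimal()
}
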