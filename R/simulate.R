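# Synthetic coalescence generator: replicated donor communities, 50:50
# mixtures with tunable engraftment bias over time, dilution-style richness
# disruption, and abiotic variables with planted drivers.

#' Scenario configuration for the coalescence simulator
#'
#' The defaults mirror the microcosm design the framework targets: two donor
#' soils mixed 1:1, 6 replicates of each donor control and of the mixture,
#' destructive sampling on days 1, 5, 15 and 30, and sequencing noise as
#' multinomial draws of 15 000 reads per sample. Donor mean profiles follow a
#' log-normal rank-abundance spectrum; the biotic dilution treatment is
#' emulated as Bernoulli feature retention at `dilution_survival` followed by
#' renormalization. The engraftment weight trajectory `w_trajectory` gives
#' donor 1's expected share of the mixture at each time; the constant 0.5
#' encodes the symmetric 50:50 null.
#'
#' @param n_features Number of features (ASVs) in the regional pool.
#' @param n_donor_reps,n_mix_reps Replicates per donor control / mixture.
#' @param times Sampling days.
#' @param w_trajectory Either a single number in \[0, 1\] or a function of
#'   time returning donor 1's expected mixture weight. See [w_linear()].
#' @param dilution Dilution label recorded in the metadata (e.g. `1e-1`).
#' @param dilution_survival Fraction of features retained by the dilution
#'   treatment (1 = undiluted). Defaults to 0.8 / 0.4 / 0.1 for dilutions
#'   1e-1 / 1e-3 / 1e-5, mimicking progressive dilution-to-extinction loss of
#'   rare taxa.
#' @param sequencing_depth Reads per sample (multinomial size).
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance spectrum of
#'   the donor mean profiles; `sdlog = 2` gives the steep, uneven spectrum
#'   typical of soil.
#' @param jitter_sd Compositional jitter: each replicate's expected profile
#'   is the mean profile perturbed by feature-wise log-normal noise with this
#'   sd, then renormalized.
#' @param dirichlet_overdispersion Extra overdispersion on top of the
#'   multinomial (0 = plain multinomial; > 0 draws replicate profiles from a
#'   Dirichlet with concentration `profile / value`).
#' @param treatment Treatment label, `"<donor1>x<donor2>"`.
#' @param abiotic_betas Named per-variable effect sizes linking abiotic
#'   deltas to community turnover in [simulate_abiotic()]. The default
#'   plants pH and nitrogen-pool effects and leaves the remaining variables
#'   inert.
#' @param abiotic_noise_sd Gaussian noise on the simulated community response.
#' @param seed Default seed used by the simulator functions when they are not
#'   given one explicitly.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_features = 500,
                            n_donor_reps = 6,
                            n_mix_reps = 6,
                            times = c(1, 5, 15, 30),
                            w_trajectory = 0.5,
                            dilution = 1e-1,
                            dilution_survival = NULL,
                            sequencing_depth = 15000,
                            abundance_meanlog = 0,
                            abundance_sdlog = 2,
                            jitter_sd = 0.15,
                            dirichlet_overdispersion = 0,
                            treatment = "AxB",
                            abiotic_betas = c(pH = 2, N_NH4 = 1.5, N_NO3 = 1.2,
                                              TN = 1, S = 0.5, OM = 0, sand = 0),
                            abiotic_noise_sd = 0.05,
                            seed = NULL) {
  if (is.numeric(w_trajectory) && length(w_trajectory) == 1L) {
    w_val <- w_trajectory
    w_trajectory <- function(t) rep(w_val, length(t))
  }
  if (!is.function(w_trajectory)) abort("`w_trajectory` must be a number or a function of time.")
  wt <- w_trajectory(times)
  if (any(wt < 0 | wt > 1)) {
    abort(sprintf("w_trajectory must stay in [0, 1]; got %s.",
                  paste(signif(wt, 3), collapse = ", ")))
  }
  if (is.null(dilution_survival)) {
    dilution_survival <- default_dilution_survival(dilution)
  }
  if (dilution_survival <= 0 || dilution_survival > 1) {
    abort("`dilution_survival` must be in (0, 1].")
  }
  donors <- treatment_donors(treatment)
  structure(
    list(n_features = n_features, n_donor_reps = n_donor_reps,
         n_mix_reps = n_mix_reps, times = times, w_trajectory = w_trajectory,
         dilution = dilution, dilution_survival = dilution_survival,
         sequencing_depth = sequencing_depth,
         abundance_meanlog = abundance_meanlog, abundance_sdlog = abundance_sdlog,
         jitter_sd = jitter_sd,
         dirichlet_overdispersion = dirichlet_overdispersion,
         treatment = treatment, donor_labels = donors,
         abiotic_betas = abiotic_betas, abiotic_noise_sd = abiotic_noise_sd,
         seed = seed),
    class = "scenario_config"
  )
}

default_dilution_survival <- function(dilution) {
  key <- format(dilution, scientific = TRUE)
  lut <- c(`1e-01` = 0.8, `1e-03` = 0.4, `1e-05` = 0.1)
  if (key %in% names(lut)) unname(lut[key]) else 1
}

#' Linear engraftment-weight trajectory
#'
#' Donor 1's expected mixture weight interpolated linearly from `from` at the
#' first configured time to `to` at the last.
#'
#' @param from,to Weights in \[0, 1\] at the first and last sampling day.
#' @return A function of time suitable for [scenario_config()].
#' @export
w_linear <- function(from, to) {
  function(t) {
    r <- range(t)
    if (diff(r) == 0) return(rep((from + to) / 2, length(t)))
    from + (to - from) * (t - r[1]) / diff(r)
  }
}

dilution_tag <- function(dilution) {
  gsub("e-0", "e-", format(dilution, scientific = TRUE))
}

# One replicate's counts: jittered expected profile, then multinomial (or
# Dirichlet-multinomial) draw at the configured depth.
draw_replicate <- function(mean_profile, config) {
  p <- mean_profile
  if (config$jitter_sd > 0) {
    p <- p * exp(rnorm(length(p), 0, config$jitter_sd))
  }
  if (config$dirichlet_overdispersion > 0) {
    conc <- p / sum(p) / config$dirichlet_overdispersion
    g <- stats::rgamma(length(p), shape = conc)
    if (sum(g) <= 0) g <- p
    p <- g
  }
  p <- p / sum(p)
  as.integer(rmultinom(1, config$sequencing_depth, p))
}

#' Simulate replicated donor control communities
#'
#' Two donor mean profiles are drawn from independent log-normal abundance
#' spectra on a shared feature space; the dilution treatment keeps each
#' feature with probability `dilution_survival` (independently per donor)
#' and renormalizes. Replicates at every configured time are jittered
#' multinomial draws at the sequencing depth.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A list with `table` (a [feature_table()]), `meta` (sample
#'   metadata), and `means` (2 x n_features matrix of donor mean profiles,
#'   rows named by donor label).
#' @export
simulate_donors <- function(config, seed = config$seed) {
  with_seed_(seed, {
    means <- vapply(config$donor_labels, function(dl) {
      spectrum <- rlnorm(config$n_features, config$abundance_meanlog,
                         config$abundance_sdlog)
      keep <- rbinom(config$n_features, 1, config$dilution_survival)
      prof <- spectrum * keep
      if (sum(prof) <= 0) {
        abort("Dilution survival removed every feature; no community left.")
      }
      prof / sum(prof)
    }, numeric(config$n_features))
    means <- t(means)
    rownames(means) <- config$donor_labels
    rows <- list(); metas <- list()
    for (dl in config$donor_labels) {
      for (t in config$times) {
        for (r in seq_len(config$n_donor_reps)) {
          id <- sprintf("%s_%s_t%s_r%s", dl, dilution_tag(config$dilution), t, r)
          rows[[id]] <- draw_replicate(means[dl, ], config)
          metas[[id]] <- tibble(sample_id = id, role = "donor",
                                soil_label = dl, treatment = NA_character_,
                                dilution = config$dilution, time_days = t,
                                replicate = as.character(r))
        }
      }
    }
    m <- do.call(rbind, rows)
    colnames(m) <- sprintf("asv%04d", seq_len(config$n_features))
    list(table = feature_table(m, kind = "taxonomic"),
         meta = dplyr::bind_rows(metas),
         means = means)
  })
}

#' Simulate the coalesced (mixture) communities
#'
#' The mixture's expected profile at time t is
#' \eqn{w(t) P_1 + (1 - w(t)) P_2} (renormalized), where \eqn{P_1, P_2} are
#' the donor mean profiles and \eqn{w} is the engraftment-weight trajectory;
#' `w = 0.5` at all times encodes the symmetric 50:50 null. Replicates are
#' jittered multinomial draws.
#'
#' @param donor_means 2 x n_features matrix (rows = donors) as produced by
#'   [simulate_donors()].
#' @param config A [scenario_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A list with `table` and `meta` for the mixture samples.
#' @export
simulate_coalescence <- function(donor_means, config, seed = config$seed) {
  if (nrow(donor_means) != 2) abort("`donor_means` must have exactly 2 rows.")
  w <- config$w_trajectory(config$times)
  if (any(w < 0 | w > 1)) abort("w(t) must stay in [0, 1].")
  with_seed_(seed, {
    rows <- list(); metas <- list()
    for (k in seq_along(config$times)) {
      t <- config$times[k]
      mixp <- w[k] * donor_means[1, ] + (1 - w[k]) * donor_means[2, ]
      mixp <- mixp / sum(mixp)
      for (r in seq_len(config$n_mix_reps)) {
        id <- sprintf("%s_%s_t%s_r%s", config$treatment,
                      dilution_tag(config$dilution), t, r)
        rows[[id]] <- draw_replicate(mixp, config)
        metas[[id]] <- tibble(sample_id = id, role = "mixture",
                              soil_label = NA_character_,
                              treatment = config$treatment,
                              dilution = config$dilution, time_days = t,
                              replicate = as.character(r))
      }
    }
    m <- do.call(rbind, rows)
    colnames(m) <- sprintf("asv%04d", seq_len(config$n_features))
    list(table = feature_table(m, kind = "taxonomic"),
         meta = dplyr::bind_rows(metas))
  })
}

#' Simulate a full coalescence scenario
#'
#' Convenience wrapper: donors plus mixtures on a shared feature space, bound
#' into one table and one metadata frame, ready for
#' [donor_outcome_distances()].
#'
#' @inheritParams simulate_donors
#' @return A list with `table`, `meta`, `donor_means`, and `config`.
#' @export
simulate_experiment <- function(config, seed = config$seed) {
  seeds <- derive_seeds(seed %||% 1L, 2)
  don <- simulate_donors(config, seed = seeds[1])
  mix <- simulate_coalescence(don$means, config, seed = seeds[2])
  tab <- feature_table(rbind(ft_matrix(don$table), ft_matrix(mix$table)),
                       kind = "taxonomic")
  list(table = tab,
       meta = dplyr::bind_rows(don$meta, mix$meta),
       donor_means = don$means,
       config = config)
}

#' Simulate abiotic variables with planted community-shift drivers
#'
#' Generates donor and mixture values for each abiotic variable (donor-level
#' means drawn once per scenario, replicate-level Gaussian noise) and a
#' community-dissimilarity response with known ground truth:
#' \deqn{bc = \mathrm{logistic}\Big(\sum_v \beta_v \, \delta_v - \bar\eta\Big) + \varepsilon,}
#' where \eqn{\delta_v} is the absolute donor-mixture difference of variable
#' v, \eqn{\beta} comes from `config$abiotic_betas`, \eqn{\bar\eta} centers
#' the linear predictor at its scenario mean (keeping the response on the
#' informative part of the logistic rather than its saturated tails), and
#' \eqn{\varepsilon} is Gaussian with sd `config$abiotic_noise_sd` (response
#' clamped to \[0, 1\]). With all betas zero the response is pure noise, so
#' [rf_importance()] should explain ~no variance; a single large beta makes
#' that variable the recoverable top driver.
#'
#' @inheritParams simulate_donors
#' @return A list with `abiotic` (tibble, one row per donor/mixture
#'   replicate: `sample_id` plus variable columns), `deltas` (delta records
#'   with the synthetic `paired_bc` response, ready for [rf_importance()]),
#'   and `betas`.
#' @export
simulate_abiotic <- function(config, seed = config$seed) {
  betas <- config$abiotic_betas
  if (length(betas) < 2) abort("`abiotic_betas` must define >= 2 variables.")
  vars <- names(betas)
  rep_sd <- 0.2  # replicate-level measurement/heterogeneity noise, z-units
  with_seed_(seed, {
    mu <- matrix(rnorm(2 * length(vars)), 2,
                 dimnames = list(config$donor_labels, vars))
    mix_mu <- colMeans(mu)
    samples <- list(); deltas <- list()
    for (t in config$times) {
      don_vals <- list()
      for (dl in config$donor_labels) {
        for (r in seq_len(config$n_donor_reps)) {
          id <- sprintf("%s_%s_t%s_r%s", dl, dilution_tag(config$dilution), t, r)
          v <- mu[dl, ] + rnorm(length(vars), 0, rep_sd)
          don_vals[[dl]][[as.character(r)]] <- v
          samples[[id]] <- tibble(sample_id = id, !!!as.list(v))
        }
      }
      for (r in seq_len(config$n_mix_reps)) {
        id <- sprintf("%s_%s_t%s_r%s", config$treatment,
                      dilution_tag(config$dilution), t, r)
        v <- mix_mu + rnorm(length(vars), 0, rep_sd)
        samples[[id]] <- tibble(sample_id = id, !!!as.list(v))
        for (dl in config$donor_labels) {
          for (dr in names(don_vals[[dl]])) {
            delta <- abs(don_vals[[dl]][[dr]] - v)
            deltas[[length(deltas) + 1L]] <- tibble(
              treatment = config$treatment, dilution = config$dilution,
              time_days = t, donor_label = dl,
              donor_replicate = dr, mixture_replicate = as.character(r),
              variable = vars, delta = unname(delta),
              eta = sum(betas * delta), broadcast = FALSE)
          }
        }
      }
    }
    deltas <- dplyr::bind_rows(deltas)
    # one response per donor/mixture pair: centered logistic link plus noise
    pairs <- dplyr::distinct(deltas[c(delta_keys, "eta")])
    pairs$paired_bc <- pmin(pmax(
      stats::plogis(pairs$eta - mean(pairs$eta)) +
        rnorm(nrow(pairs), 0, config$abiotic_noise_sd), 0), 1)
    deltas <- dplyr::left_join(deltas, pairs[c(delta_keys, "paired_bc")],
                               by = delta_keys)
    deltas$eta <- NULL
    list(abiotic = dplyr::bind_rows(samples),
         deltas = deltas,
         betas = betas)
  })
}
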