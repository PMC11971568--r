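# coalescr

Quantifying donor contributions to microbial community coalescence.

When two entire microbial communities are mixed together with their
environments — soil coalescence, fecal microbiota transplantation, river
confluences — the reassembled outcome community resembles each donor to a
different degree. `coalescr` implements a beta-diversity framework for
measuring that resemblance and tracking it over time, for microbial
ecologists working with replicated coalescence experiments (amplicon count
tables, carbon-substrate utilization profiles, enzyme panels, soil
chemistry).

## The framework

For a treatment `I x II` at sampling day *t*, the package computes **all**
donor-replicate-to-mixture-replicate distances

```
d(I_rep_i, mix_rep_j)   and   d(II_rep_i, mix_rep_j)      i = 1..n_I, j = 1..n_mix
```

under a chosen metric — Jensen-Shannon distance (default:
`sqrt(JSD_base2) ∈ [0, 1]` with `JSD(p,q) = ½KL(p‖m) + ½KL(q‖m)`,
`m = ½(p+q)`), Bray-Curtis `Σ|x−y| / Σ(x+y)`, Euclidean, cosine, or Earth
Mover's distance (exact transportation solver for arbitrary ground costs).
Smaller distances mean a larger donor contribution. On top of the distance
records:

* **Dominance per stratum** — Shapiro-Wilk normality gate, then Welch's
  t-test or Mann-Whitney U; the donor with the significantly smaller mean
  distance dominates (α = 0.05).
* **Trends** — OLS of distance on time; a significantly negative slope is an
  increasing contribution.
* **Structure-function coupling** — Spearman correlation between structural
  and functional distance records joined on the replicate-pair key.
* **Abiotic drivers** — per-variable absolute deltas |donor − mixture|
  against paired Bray-Curtis community distances in a random-forest
  regression; %IncMSE importance with response-permutation p-values.
* **Supporting machinery** — permuted rarefaction to a fixed depth, Biolog
  EcoPlate OD normalization, PCoA, one-way PERMANOVA (999 permutations), and
  a synthetic microcosm generator with tunable engraftment bias `w(t)` for
  end-to-end validation.

## Worked example

Simulate a coalescence scenario in which donor A's engraftment weight climbs
from 0.5 to 0.9 over the 30-day experiment, then ask the framework what
happened:

```r
library(coalescr)

cfg  <- scenario_config(w_trajectory = w_linear(0.5, 0.9), seed = 42)
sim  <- simulate_experiment(cfg)
recs <- donor_outcome_distances(sim$table, sim$meta, metric = "jsd")

dominance_test(recs)[, c("time_days", "mean_dist_1", "mean_dist_2",
                         "method", "p_value", "stars", "dominant")]
#>   time_days mean_dist_1 mean_dist_2       method   p_value stars dominant
#> 1         1       0.526       0.511 mann_whitney  3.35e-03    **        B
#> 2         5       0.476       0.565 mann_whitney  3.05e-13  ****        A
#> 3        15       0.390       0.647 mann_whitney  3.05e-13  ****        A
#> 4        30       0.229       0.809      welch_t 1.70e-116  ****        A

contribution_trend(recs)[, c("donor_label", "slope", "p_value", "direction")]
#>   donor_label   slope   p_value               direction
#> 1           A -0.0101 7.45e-140 increasing_contribution
#> 2           B  0.0100 2.97e-133 decreasing_contribution
```

Donor A's distance to the outcome shrinks from ~0.53 to ~0.23 (its
contribution grows) while donor B's grows symmetrically — the planted
takeover, recovered. The same pattern plots with
`plot_contribution(recs, dominance_test(recs))`.

Abiotic drivers, with a planted pH effect:

```r
ab  <- simulate_abiotic(scenario_config(
         abiotic_betas = c(pH = 3, OM = 0, sand = 0, TN = 0),
         abiotic_noise_sd = 0.05, seed = 42))
imp <- rf_importance(ab$deltas, n_trees = 500,
                     n_response_permutations = 50, seed = 42)
imp
#> <coalescr_rfimp> 288 obs, 500 trees, 50 response permutations
#> variance explained: 82.2%
#>   variable pct_inc_mse p_value stars
#> 1 pH           762.     0.0196 *
#> 2 TN             8.65   0.196  ns
#> 3 OM             0.615  0.471  ns
#> 4 sand          -7.76   0.686  ns
```

Only the planted driver is significant, and the forest explains 82% of the
community turnover. `tidy()` and `glance()` methods give the same content as
tibbles; `plot_importance(imp)` draws the bar plot.

A command-line interface wraps the same functions
(`inst/exec/coalescr <subcommand>`; subcommands `simulate`, `rarefy`,
`distances`, `contribution`, `trends`, `coupling`, `abiotic-rf`,
`permanova`, `pcoa`), writing TSV outputs plus a JSON manifest with the seed
and input checksums for bit-for-bit reproducibility.

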