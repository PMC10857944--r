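# camtrapTI

Analysis tools for multi-species camera-trap surveys of ungulate
communities, built around three questions ecologists ask of such data:

1. **How often is each species detected, and where?** Raw time-stamped
   images are collapsed into independent *contacts* — the first image of a
   sequence, or an image of the same species separated from the previous one
   by more than an independence window (30 min by default). Per-species
   summaries report naive occupancy, total contacts, per-station detection
   rates (contacts per trap-day) and the average number of trap-days needed
   to photograph the species once.

2. **Which land covers does each species prefer, and does human activity
   matter?** Per-station contact counts `y_i` are modelled with a negative
   binomial GLM with a log link:

   `y_i ~ NB(mu_i, theta)`, `log(mu_i) = beta_0 + beta_landcover(i) + beta_h * h_i + log(d_i)`

   where `h_i` is the station's human detection rate (contacts/day), and the
   log deployment duration `log(d_i)` enters as an offset so coefficients
   are log detection-*rate* differences relative to the reference land cover
   (clearfell). Overdispersion is diagnosed with the Pearson dispersion
   ratio of the Poisson fit; estimated marginal means give model-predicted
   contacts/day per land cover and all 15 pairwise contrasts; cells with no
   contacts are separation-flagged rather than regularized away.

3. **Does one species follow another?** For a directed pair
   (leader, follower), the observed statistic is the median time from each
   follower contact back to the most recent preceding leader contact at the
   same station, pooled over stations. A null distribution of 1000 such
   medians is built by re-timestamping follower contacts with dates drawn
   uniformly from each station's active dates and times drawn from the
   follower's diel activity pattern. With `Q` the proportion of null medians
   greater than the observed median, the two-sided p-value is
   `p = min(Q, 1 - Q) * 2`; a positive percent difference
   `100 * (median_null - observed) / median_null` points in the attraction
   direction.

A synthetic survey generator (`simulate_survey()`, `preset_paper_like()`)
with land-cover-dependent overdispersed intensities, von Mises diel
profiles, human disturbance and optional injected leader–follower
attraction makes every stage testable end-to-end without field data.

## Worked example

```r
library(camtrapTI)

sim <- simulate_survey(preset_paper_like(seed = 42))   # 39 stations, 28 days
ds  <- sim$dataset                                     # or read_survey(...)
ct  <- filter_independent(ds, window_minutes = 30)

species_summary_table(ct, ds)
#>     species naive_occupancy_pct total_contacts mean_detection_rate sd_detection_rate days_per_contact
#>    red_deer            43.58974             32          0.02930403         0.0490729        34.125000
#>    roe_deer            66.66667            142          0.13003663         0.2112071         7.690141
#>   sika_deer            84.61538            626          0.57326007         0.6204831         1.744409
#>   wild_boar            30.76923            165          0.15109890         0.4439942         6.618182
```

Naive occupancy is the percentage of operating stations with at least one
contact; `days_per_contact` is total trap-days over total contacts (1.74
days of effort per sika deer photograph here).

```r
fit <- fit_detection_model(ct, ds, "sika_deer")
fit
#> Detection-rate model (negative binomial GLM, log link, log-effort offset): sika_deer
#>   reference land cover: clearfell; stations: 39
#>   theta = 0.748; Nagelkerke R2 = 0.23
#>                             term estimate std_error p_value rate_ratio separation
#>                      (Intercept)   -2.943     1.004  0.0034       0.05      FALSE
#>  land_coverconiferous_plantation    2.502     1.084  0.0210      12.21      FALSE
#>              land_covergrassland    2.715     1.091  0.0130      15.10      FALSE
#>    land_coverheathland_shrubland    1.885     1.117  0.0910       6.59      FALSE
#>                land_coverwetland    0.773     1.156  0.5000       2.17      FALSE
#>               land_coverwoodland    2.605     1.076  0.0160      13.53      FALSE
#>                       human_rate    0.143     0.591  0.8100       1.15      FALSE
```

The rate-ratio column is `exp(estimate)`: this simulated sika population is
detected about 12.2 times more often in coniferous plantation than in
clearfell. `emm_contrasts(fit)` adds the per-land-cover predicted rates and
the 15 pairwise comparisons.

```r
interval_test(ct, "roe_deer", "sika_deer", ds, reps = 1000, seed = 42)
#> Time-interval test: roe_deer (leader) -> sika_deer (follower)
#>   observed median interval: 14.69 h over 383 intervals
#>   null median: 62.00 h (95% band 52.07-71.93 h; 1000 replicates, 0 invalid)
#>   observed 76.3% shorter (attraction direction) than expected; Q = 1.000, two-sided p < 0.001
```

The preset injects a roe-to-sika attraction (40% of sika events placed at
an exponential lag, mean 2 h, after a roe event), and the test recovers it:
the observed median is far below the entire null band. `run_all_pairs()`
runs all 12 directed pairs of the four species with independent RNG
substreams, and `run_pipeline()` (or `inst/scripts/run-pipeline.R` from a
shell) orchestrates every stage from two CSV files to a report directory.

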