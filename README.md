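# fossilspread

Spatially standardized fossil diversity estimation for palaeobiologists.

Apparent species richness in the fossil record scales with the geographic
spread of the localities that happen to have been sampled — the ubiquitous
species–area effect. Time bins whose collections span half a continent will
look richer than bins sampled from a single basin, whatever the underlying
biology did. `fossilspread` removes this artefact by drawing fossil
localities to an *equal palaeogeographic spread* before estimating richness,
so that diversity comparisons through time and across regions are made at
comparable points on the species–area curve.

## What it does

- **Spread metric.** Localities are binned to 1° grid cells and spread is
  measured as summed minimum-spanning-tree (MST) length over the occupied
  cell centroids (great-circle distances, spherical Earth, R = 6371 km;
  1° of latitude ≈ 111.19 km).
- **Regionalization.** The global per-bin MST is split into continental-scale
  subtrees by iteratively removing the longest branch of any component whose
  summed length is at or above a ceiling (default 13,000 km), then dropping
  fragments too small to sample; user-supplied biogeographic barrier edges
  can also be cut.
- **Equal-spread subsampling.** From each regional subtree, replicate samples
  (default 20) grow from random starting cells along MST adjacency until the
  induced tree length reaches a target (default 3,200 km ± 10%).
- **Richness estimation.** Per sample and per unstandardized regional pool:
  raw counts; shareholder quorum subsampling (SQS, coverage-based rarefaction
  at quorum *q* = 0.4, coverage estimated by Good's
  *u* = 1 − singletons/occurrences); and TRiPS, which models per-taxon
  sampling as Poisson(λ), solves λ/(1 − e^(−λ)) = mean count, and estimates
  richness as n_obs/(1 − e^(−λ̂)) with a profile-likelihood × binomial 95%
  interval.
- **Trend models.** Log-link regressions of richness on bin-midpoint age
  (negative binomial for counts, Gaussian for SQS/TRiPS), reporting the
  slope (per myr; negative = increase towards the present), its standard
  error and Wald P, ln increase = |slope| × span, percent increase
  = 100(e^ln − 1), and Bonferroni-corrected P values.
- **Synthetic worlds with known truth.** A generator builds toy occurrence
  tables with species–area structure (clustered collections, circular
  species ranges, uneven abundances, reference groupings) so the whole
  workflow can be validated against ground truth.

## Worked example

The record-bias experiment: a synthetic world whose *true* richness is
identical in every time bin, but whose sampled window doubles in extent
across eight 9-myr bins.

```r
library(fossilspread)

w   <- heterogeneous_sampling_scenario(world_config(seed = 21))
cfg <- pipeline_config(world = w$config, n_reps = 20, master_seed = 21)
res <- run_pipeline(cfg)
print(res)
#> Spatially standardized diversity analysis
#>   occurrences (cleaned, binned): 5027
#>   regional pools: 8
#>   accepted equal-spread samples: 160
#>   trend fits:
#>                series         slope     p_slope percent_increase
#>    raw_unstandardized -0.0070794776 0.000505637               56
#>      raw_standardized  0.0012524814 0.634969391                8
#>    sqs_unstandardized -0.0048681365 0.003677651               36
#>      sqs_standardized  0.0004645253 0.672343016                3
#>  trips_unstandardized -0.0073917785 0.001461196               59
#>    trips_standardized  0.0009854826 0.492718223                6
```

Read the table: with *unstandardized* spread, raw richness shows a highly
significant apparent rise through time (slope −0.0071 per myr, P ≈ 0.0005,
implying a spurious +56% over the series) — pure species–area artefact,
since true richness is constant. After equal-spread standardization every
series is statistically flat (P ≈ 0.5–0.7, implied changes of 3–8%). The
per-sample detail sits in `res$richness_standardized`,
`res$richness_unstandardized`, `res$manifest` (replicate acceptance) and
`res$spread` (spread metrics per region × bin); `run_pipeline()` writes all
of them as CSV when `out_dir` is set.

Reading real data instead of simulating:

```r
cfg <- pipeline_config(input = "occurrences.csv",   # PaleoDB download headers
                       bins = default_time_bins(),  # packaged ~9-myr Tr1-Pg2 scheme
                       out_dir = "results")
res <- run_pipeline(cfg)
```

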