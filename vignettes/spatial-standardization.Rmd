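---
title: "Spatially standardized fossil diversity estimation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially standardized fossil diversity estimation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fossilspread)
```

## The problem

Species richness scales with sampled area. In fossil occurrence data the
"area" actually sampled — the palaeogeographic spread of fossil localities —
varies enormously among time intervals and regions, so raw or even
coverage-subsampled richness series confound biology with the geography of
collecting. Comparing a time bin whose collections span half a continent with
one whose collections cluster in a single basin compares different points on
the species–area curve.

`fossilspread` addresses this by standardizing the *spatial spread* of
localities before any richness estimation. Spread is quantified as summed
minimum-spanning-tree (MST) length: occurrences are binned to 1° grid cells,
and the MST over the occupied cell centroids (great-circle edge weights,
spherical Earth of radius 6371 km) gives the minimum total length of segments
connecting all localities. Gridding first removes the summed contribution of
small-scale inter-locality distances; summed MST length then captures a
combination of spatial coverage, dispersion and total extent, and correlates
tightly with convex-hull area, maximum great-circle distance, standard
distance and occupied-cell counts (`metric_correlations()` lets you verify
this on your own pools).

## The workflow

1. **Clean and bin** (`read_occurrence_table()`, `apply_taxon_filters()`,
   `assign_time_bins()`). Records that are generically indeterminate, flagged
   (marine, flying, ichnotaxa, ootaxa, soft-tissue preservation) or on a
   user-supplied wastebasket list are removed with a per-category tally.
   A record enters a time bin only when its age interval lies *entirely*
   within the bin; ages exactly equal to a boundary count as inside (closed
   containment, matching the inclusive-bounds convention of occurrence
   databases). Duplicate listings of a taxon within one collection collapse
   to a single occurrence.
2. **Grid and measure spread** (`bin_to_grid()`, `build_mst()`,
   `spread_metrics()`). Cells are equal-angle 1° (indices by `floor`,
   anchored at 0°); the grid is deliberately not equal-area, because most
   collections lie at temperate palaeolatitudes where the distortion is
   modest, and because this matches long-standing practice for occurrence
   gridding.
3. **Split the global MST into regions** (`split_global_mst()`). While any
   connected component's summed length is at or above a *ceiling* (default
   13,000 km, sized to isolate continental regions), that component's longest
   edge is removed; ties break towards the lexicographically smaller cell
   pair so splitting is deterministic. Components below the minimum sample
   size are dropped. Remaining branches crossing biogeographic barriers can
   be cut with a user-supplied edge list (`remove_barrier_edges()`); the
   package does not attempt to encode that expert judgement itself.
4. **Grow equal-spread samples** (`grow_spatial_sample()`,
   `replicate_spatial_samples()`). From a uniformly random starting cell, the
   sample repeatedly adds the frontier cell joined to it by the shortest MST
   edge, until the induced subtree length reaches the target (default
   3,200 km ± 10%). Because discrete localities rarely land exactly on the
   target, the state with or without the final cell — whichever is closer —
   is accepted, provided it lies in the tolerance band. Twenty replicate
   samples per region × bin are drawn by default.
5. **Estimate richness** (`estimate_richness()`, `estimate_all()`): raw
   counts, coverage-based subsampling (SQS) at quorum 0.4, and the
   zero-truncated-Poisson maximum-likelihood estimator (TRiPS), each with the
   pool's sampling diagnostics (Good's *u*, dominance). Estimates from pools
   linked to fewer than 20 distinct references are flagged unreportable
   rather than deleted.
6. **Fit trends** (`fit_trend()`, `trend_table()`): log-link models of
   richness against bin-midpoint age — negative binomial for raw counts,
   Gaussian for the continuous SQS/TRiPS estimates. Time counts down towards
   the present, so a negative slope is an *increase*; `ln_increase` is
   |slope| × series span and `percent_increase` is 100(e^ln − 1). Bonferroni
   corrections are reported alongside the raw P values.

`run_pipeline()` chains all of this deterministically from a single
`pipeline_config()` (one master seed feeds every stochastic stage), and a
thin command-line wrapper is installed at `inst/scripts/fossilspread.R`.

## Estimator details

**Good's *u*** is 1 − singletons/occurrences, where a singleton is by
default a taxon found in exactly one *collection* (the convention for
occurrence-level subsampling); a by-occurrence variant is exposed for
sensitivity analyses. *u* estimates the coverage of the sampling pool and
caps the achievable quorum: a pool whose *u* falls below the quorum yields a
flagged not-available estimate rather than a misleading number.

**SQS.** Each trial draws whole collections in uniformly random order and
accumulates the occurrence-frequency shares (from the full pool) of each
newly seen taxon. The accumulated share, multiplied by *u* to convert
observed coverage into coverage of the true pool, is compared against the
quorum; drawing stops at the first crossing and the trial's richness is the
count of distinct taxa drawn. The estimate is the mean over `n_trials`
(default 100 — the trial count is a precision knob, not a scientific
parameter; tests use up to 4,000). An option to ignore the dominant taxon's
share exists but defaults off. On a three-collection pool the estimate
matches the exhaustive expectation over all collection orders (a unit test
enforces this).

**TRiPS.** Per-taxon occurrence counts are modelled as Poisson(λ) sampling,
so observed counts are zero-truncated Poisson. The MLE solves
λ/(1 − e^(−λ)) = mean(count) by bracketed root finding with Newton polishing
(residual < 1e−10); a pool of all-singleton counts sits on the λ = 0 boundary
and is flagged degenerate. Detection probability is p = 1 − e^(−λ) and
estimated richness n_obs/p. The 95% interval combines a χ²(1)
profile-likelihood interval on λ with binomial uncertainty in n_obs, by
inverting the binomial at the profile bounds of p on both sides. Combining
two 95% sources makes the interval conservative: simulated coverage at
N = 200, λ = 1 is ≈ 99%, not 95% — the interval errs towards honesty about
what the data exclude.

**Trends.** Gaussian log-link fits use the exact exponential as a starting
value and recover noiseless exponential series to numerical precision;
negative-binomial dispersion is estimated jointly by maximum likelihood
(`MASS::glm.nb`). Replicate-aggregated richness enters as one point per
region × bin (the mean across accepted replicates; the mean was chosen over
the median as the conventional summary of replicate subsamples).

## The synthetic world

Real occurrence data cannot reveal whether a correction works, because the
truth is unknown. The generator (`world_config()`, `generate_world()`)
builds toy worlds where it is known: a fixed pool of species (default 400)
with lognormal abundances (meanlog 0, sdlog 0.8), circular geographic
ranges (centres uniform over a 60° × 90° region, radii lognormal with median
800 km), sampled by collections from a Thomas-like clustered point process
(default 80 collections per bin around 10 parents, cluster sd 150 km) inside
a per-bin sampling window. Each collection yields zero-truncated-Poisson(10)
occurrences drawn from the species whose ranges cover it, weighted by
abundance; references group 1 + Poisson(0.5) collections each. Default bins
are eight 9-myr intervals. Window half-extents default to 5° × 8° so that
even a doubled window remains a *single* continental-scale region — its
global MST stays below the 13,000 km ceiling — which is the regime the
equal-spread method addresses.

`heterogeneous_sampling_scenario()` is the record-bias experiment: the
species pool is constant while the window doubles across bins, so any raw
richness trend is pure species–area artefact. The generator deliberately
omits features of real data: no plate motion, no preservation or
taxonomic error, no temporal range structure in species, no latitudinal
diversity gradient, and collection density that is statistically stationary
within a window. Passing tests therefore show that the workflow removes a
*pure* spatial-sampling artefact under known conditions; they cannot show
how it interacts with the additional biases of real occurrence data.

## Numerical choices and edge cases

- Earth is a sphere of radius 6371.0 km; one degree of latitude is
  ≈ 111.19 km. No ellipsoid, no Steiner trees.
- Longitudes normalize into (−180°, 180°]; cells on the domain edge fold
  into the topmost/rightmost cell so indices stay in range.
- The geographic mean point is the renormalized mean of 3-D unit vectors,
  avoiding lat/lon averaging artefacts near the antimeridian; standard
  distance is the RMS great-circle distance from that point; convex hulls
  are computed on a Lambert azimuthal equal-area projection about it, and
  fewer than three non-collinear cells report area 0 with a degenerate flag.
- MST construction is Prim's algorithm on the complete centroid graph; all
  ties (equal edges in building, splitting and growth) break towards the
  lexicographically smaller cell pair, so every spatial result is
  deterministic given the input.
- Sample growth tracks the *induced subtree length*, which is monotone
  non-decreasing by construction — the natural reading of growing a sample
  "until the target MST length is reached". Growing by raw geographic
  proximity instead of tree adjacency, or re-measuring a fresh MST of the
  sampled cells, are defensible alternatives; tree adjacency was chosen
  because it guarantees connected samples and monotone spread.
- A rejected replicate (acceptance band missed) is retried from a fresh
  random start up to 100 times; a subtree with no acceptances is reported
  unsampleable, never fatal. The minimum subtree size for sampling defaults
  to the lower edge of the acceptance band, target × (1 − tol).
- The reference threshold is ≥ 20 by default and configurable, reflecting
  genuine ambiguity between "at least 20" and "more than 20" in common
  usage of this filter.
- All randomness flows from explicit seeds; replicate streams derive from a
  master seed, so every analysis is reproducible bit-for-bit.

## Problem sizes used in the tests

The suite validates against independent oracles at small sizes (exhaustive
spanning-tree enumeration up to 7 cells; exhaustive permutation expectation
for a 3-collection SQS pool), checks parameter recovery at moderate sizes
(500 TRiPS assemblages of 200 species; 200 simulated trend series), and runs
the record-bias experiment end-to-end on 100 synthetic worlds of roughly
5,000 occurrences each with 10 replicate samples per region × bin and 40 SQS
trials. These sizes were chosen so the whole suite completes in a few
minutes while keeping Monte-Carlo error well below the tested margins.

## Known limitations

- Equal summed MST length is not equal area: in sparsely sampled windows the
  same tree length spans fewer, farther-apart cells and hence a somewhat
  larger hull. Standardization reduces spread variance roughly an order of
  magnitude in the synthetic worlds; it does not eliminate every residual
  density effect.
- Palaeocoordinates are consumed, not computed: the package performs no
  plate rotation.
- Wastebasket taxa, marine/flying assignments and biogeographic barriers are
  user inputs; the package deliberately hard-codes no taxonomy.
- The packaged Tr1–Pg2 bin scheme is an approximate ~9-myr construction from
  ICS stage boundaries, intended as a sensible default rather than an
  authority.
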