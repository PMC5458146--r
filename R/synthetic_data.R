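#' Synthetic time-bin scheme
#'
#' Equal-duration bins for synthetic worlds (default: eight 9-myr bins from
#' 250 Ma), labelled "B1" (oldest) onwards.
#'
#' @param n_bins number of bins.
#' @param oldest_ma age of the oldest bin's base, Ma.
#' @param duration_myr bin duration.
#' @return a `time_bins` data.frame.
#' @export
synthetic_time_bins <- function(n_bins = 8, oldest_ma = 250, duration_myr = 9) {
  start <- oldest_ma - (seq_len(n_bins) - 1) * duration_myr
  time_bins(paste0("B", seq_len(n_bins)), start, start - duration_myr)
}

#' Configuration of a synthetic fossil world
#'
#' Describes a toy world with known truth: a fixed regional species pool in
#' which species have circular geographic ranges and uneven (lognormal or
#' log-series) abundances, and fossil collections are laid down by a
#' Thomas-like clustered point process inside a per-bin sampling window.
#' Because species density is uniform through time, richness observed in a
#' window grows with window size -- the species-area artefact the
#' equal-spread workflow is designed to remove. Defaults are sized so that a
#' full world (roughly 2,000-3,000 occurrences) generates and analyses in
#' seconds.
#'
#' @param n_species size of the regional species pool (default 400).
#' @param abundance_model `"lognormal"` or `"log_series"`.
#' @param abundance_pars parameters: `meanlog`/`sdlog` (lognormal, defaults
#'   0 / 0.8) or `theta` in (0,1) (log-series).
#' @param centre_lat_range,centre_lon_range box over which species range
#'   centres are uniform (degrees; defaults lat [-30, 30], lon [-45, 45]).
#' @param radius_meanlog,radius_sdlog lognormal parameters of species range
#'   radii in km (defaults log(800) and 0.6: median range radius 800 km).
#' @param n_collections collections per bin (default 80).
#' @param n_parents Thomas-process parent count per bin (default 10).
#' @param offspring_sd_km cluster spread around each parent (default 150 km).
#' @param occ_mean mean occurrences per collection (zero-truncated Poisson,
#'   default 10).
#' @param refs_mean references group collections: collections per reference
#'   is 1 + Poisson(`refs_mean`) (default 0.5: most references report one
#'   or two collections, as is typical of occurrence databases).
#' @param bins a `time_bins` scheme (default [synthetic_time_bins()]).
#' @param trajectory per-bin true-richness trajectory: `list(type =
#'   "constant")`, `list(type = "exponential", rate = r)` (per myr, towards
#'   the present) or `list(type = "step", factor = f, at_bin = k)`.
#' @param window_half_lat,window_half_lon half-extent of the base sampling
#'   window, degrees (defaults 5 and 8; the window is centred on (0, 0),
#'   sized so that even a doubled window stays a single continental-scale
#'   region).
#' @param spread_multipliers per-bin linear scaling of the sampling window
#'   (default all 1); this is the knob that induces a pure species-area
#'   artefact while the species pool stays fixed.
#' @param seed integer RNG seed.
#' @return list of class `world_config`.
#' @export
world_config <- function(n_species = 400,
                         abundance_model = c("lognormal", "log_series"),
                         abundance_pars = list(meanlog = 0, sdlog = 0.8),
                         centre_lat_range = c(-30, 30),
                         centre_lon_range = c(-45, 45),
                         radius_meanlog = log(800), radius_sdlog = 0.6,
                         n_collections = 80, n_parents = 10,
                         offspring_sd_km = 150, occ_mean = 10, refs_mean = 0.5,
                         bins = synthetic_time_bins(),
                         trajectory = list(type = "constant"),
                         window_half_lat = 5, window_half_lon = 8,
                         spread_multipliers = NULL, seed = 1) {
  abundance_model <- match.arg(abundance_model)
  if (is.null(spread_multipliers)) spread_multipliers <- rep(1, nrow(bins))
  stopifnot(n_species >= 1, n_collections >= 1, n_parents >= 1,
            occ_mean > 0, refs_mean >= 0, offspring_sd_km > 0,
            length(spread_multipliers) == nrow(bins),
            all(spread_multipliers > 0))
  structure(list(n_species = n_species, abundance_model = abundance_model,
                 abundance_pars = abundance_pars,
                 centre_lat_range = centre_lat_range,
                 centre_lon_range = centre_lon_range,
                 radius_meanlog = radius_meanlog, radius_sdlog = radius_sdlog,
                 n_collections = n_collections, n_parents = n_parents,
                 offspring_sd_km = offspring_sd_km, occ_mean = occ_mean,
                 refs_mean = refs_mean, bins = bins, trajectory = trajectory,
                 window_half_lat = window_half_lat,
                 window_half_lon = window_half_lon,
                 spread_multipliers = spread_multipliers, seed = seed),
            class = "world_config")
}

KM_PER_DEG <- pi * EARTH_RADIUS_KM / 180

trajectory_factors <- function(trajectory, bins) {
  n <- nrow(bins)
  switch(trajectory$type,
         constant = rep(1, n),
         exponential = {
           # rate per myr of increase towards the present
           el <- (bins$midpoint_ma[1] - bins$midpoint_ma) * trajectory$rate
           exp(el)
         },
         step = {
           f <- rep(1, n)
           f[seq_len(n) >= trajectory$at_bin] <- trajectory$factor
           f
         },
         stop("unknown trajectory type: ", trajectory$type))
}

rztpois <- function(n, lambda) {
  # inverse-CDF draw conditioned on > 0 (one uniform per value)
  u <- stats::runif(n, stats::dpois(0, lambda), 1)
  stats::qpois(u, lambda)
}

#' Generate a synthetic fossil-occurrence world
#'
#' Simulates the world described by a [world_config()] and emits an
#' occurrence table in the package's canonical columns (writable in the
#' PaleoDB dialect via [write_occurrence_table()]) together with a truth
#' record: the true species pool per bin, the species available to each
#' bin's sampling window, and the species actually sampled.
#'
#' @param cfg a [world_config()].
#' @return list of class `fossil_world`: `occurrences`, `truth` (list with
#'   `per_bin` data.frame and `species` data.frame), `config`.
#' @export
generate_world <- function(cfg) {
  stopifnot(inherits(cfg, "world_config"))
  with_local_seed(cfg$seed, {
    bins <- cfg$bins
    factors <- trajectory_factors(cfg$trajectory, bins)
    pool_sizes <- pmax(1L, as.integer(round(cfg$n_species * factors)))
    n_max <- max(pool_sizes)
    ab <- switch(cfg$abundance_model,
                 lognormal = stats::rlnorm(n_max, cfg$abundance_pars$meanlog,
                                           cfg$abundance_pars$sdlog),
                 log_series = {
                   theta <- cfg$abundance_pars$theta
                   stopifnot(theta > 0, theta < 1)
                   # P(k) proportional to theta^k / k, truncated at 1000
                   k <- 1:1000
                   pk <- theta^k / k
                   sample(k, n_max, replace = TRUE, prob = pk)
                 })
    species <- data.frame(
      species_id = seq_len(n_max),
      taxon_name = sprintf("Synthetica species%04d", seq_len(n_max)),
      abundance = ab,
      centre_lat = stats::runif(n_max, cfg$centre_lat_range[1], cfg$centre_lat_range[2]),
      centre_lon = stats::runif(n_max, cfg$centre_lon_range[1], cfg$centre_lon_range[2]),
      radius_km = stats::rlnorm(n_max, cfg$radius_meanlog, cfg$radius_sdlog),
      stringsAsFactors = FALSE)
    occ_rows <- vector("list", nrow(bins))
    truth_rows <- vector("list", nrow(bins))
    coll_counter <- 0L
    ref_counter <- 0L
    occ_counter <- 0L
    for (b in seq_len(nrow(bins))) {
      n_pool <- pool_sizes[b]
      sp <- species[seq_len(n_pool), , drop = FALSE]
      m <- cfg$spread_multipliers[b]
      hlat <- cfg$window_half_lat * m
      hlon <- cfg$window_half_lon * m
      n_coll <- cfg$n_collections
      par_lat <- stats::runif(cfg$n_parents, -hlat, hlat)
      par_lon <- stats::runif(cfg$n_parents, -hlon, hlon)
      sd_deg <- cfg$offspring_sd_km / KM_PER_DEG
      lat <- numeric(n_coll)
      lon <- numeric(n_coll)
      covering <- vector("list", n_coll)
      for (i in seq_len(n_coll)) {
        tries <- 0L
        repeat {
          tries <- tries + 1L
          p <- sample.int(cfg$n_parents, 1)
          la <- par_lat[p] + stats::rnorm(1, 0, sd_deg)
          lo <- par_lon[p] + stats::rnorm(1, 0, sd_deg / cos(par_lat[p] * pi / 180))
          la <- min(max(la, -89.5), 89.5)
          lo <- normalize_lon(lo)
          cov <- which(great_circle_km(la, lo, sp$centre_lat, sp$centre_lon) <=
                         sp$radius_km)
          if (length(cov) > 0) break
          if (tries >= 1000)
            stop("could not place a collection covered by any species range",
                 call. = FALSE)
        }
        lat[i] <- la; lon[i] <- lo
        covering[[i]] <- cov
      }
      # references partition the shuffled collections
      ref_sizes <- integer(0)
      while (sum(ref_sizes) < n_coll)
        ref_sizes <- c(ref_sizes, 1L + stats::rpois(1, cfg$refs_mean))
      ref_of_coll <- rep(seq_along(ref_sizes), ref_sizes)[seq_len(n_coll)]
      ref_of_coll <- ref_of_coll[sample.int(n_coll)]
      n_occ <- rztpois(n_coll, cfg$occ_mean)
      bin_rows <- vector("list", n_coll)
      for (i in seq_len(n_coll)) {
        cov <- covering[[i]]
        taxa_i <- if (length(cov) == 1) rep(cov, n_occ[i]) else
          sample(cov, n_occ[i], replace = TRUE, prob = sp$abundance[cov])
        mid_age <- stats::runif(1, bins$end_ma[b] + 0.6, bins$start_ma[b] - 0.6)
        bin_rows[[i]] <- data.frame(
          occurrence_id = sprintf("o%06d", occ_counter + seq_along(taxa_i)),
          collection_id = sprintf("c%05d", coll_counter + i),
          taxon_name = sp$taxon_name[taxa_i],
          taxon_rank = "species",
          reference_id = sprintf("r%05d", ref_counter + ref_of_coll[i]),
          palaeolat = lat[i],
          palaeolon = lon[i],
          interval_max_ma = mid_age + 0.5,
          interval_min_ma = mid_age - 0.5,
          stringsAsFactors = FALSE)
        occ_counter <- occ_counter + length(taxa_i)
      }
      occ_b <- do.call(rbind, bin_rows)
      occ_rows[[b]] <- occ_b
      coll_counter <- coll_counter + n_coll
      ref_counter <- ref_counter + max(ref_of_coll)
      # species whose range circle reaches the sampling window (clamp the
      # centre to the window rectangle, then test the great-circle distance)
      cl_lat <- pmin(pmax(sp$centre_lat, -hlat), hlat)
      cl_lon <- pmin(pmax(sp$centre_lon, -hlon), hlon)
      available <- sum(great_circle_km(sp$centre_lat, sp$centre_lon,
                                       cl_lat, cl_lon) <= sp$radius_km)
      truth_rows[[b]] <- data.frame(
        bin = bins$name[b],
        midpoint_ma = bins$midpoint_ma[b],
        spread_multiplier = m,
        n_species_pool = n_pool,
        n_species_available = available,
        n_species_sampled = length(unique(occ_b$taxon_name)),
        n_occurrences = nrow(occ_b),
        stringsAsFactors = FALSE)
    }
    occurrences <- do.call(rbind, occ_rows)
    for (f in FLAG_FIELDS) occurrences[[paste0("flag_", f)]] <- FALSE
    rownames(occurrences) <- NULL
    truth <- list(per_bin = do.call(rbind, truth_rows), species = species)
    rownames(truth$per_bin) <- NULL
    structure(list(occurrences = occurrences, truth = truth, config = cfg),
              class = "fossil_world")
  })
}

#' @export
print.fossil_world <- function(x, ...) {
  cat("Synthetic fossil world:", nrow(x$occurrences), "occurrences,",
      length(unique(x$occurrences$taxon_name)), "sampled species,",
      nrow(x$config$bins), "time bins\n")
  invisible(x)
}

#' Write / read a world truth record as JSON
#'
#' @param truth the `truth` element of a `fossil_world`.
#' @param path JSON file path.
#' @return `path` invisibly (write); the truth list (read).
#' @export
write_world_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_world_truth
#' @export
read_world_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(per_bin = as.data.frame(x$per_bin, stringsAsFactors = FALSE),
       species = as.data.frame(x$species, stringsAsFactors = FALSE))
}

#' Simulate per-taxon counts under the TRiPS sampling model
#'
#' Draws Poisson(lambda) occurrence counts for `n_species` true species and
#' drops the unobserved (zero-count) ones -- the exact generative model the
#' TRiPS estimator inverts.
#'
#' @param n_species true species count.
#' @param lambda per-bin sampling rate (> 0).
#' @param rng_seed optional seed.
#' @return integer vector of zero-truncated counts with attributes
#'   `true_n` (= `n_species`) and `n_unobserved`.
#' @export
generate_trips_counts <- function(n_species, lambda, rng_seed = NULL) {
  stopifnot(lambda > 0, n_species >= 1)
  counts <- with_local_seed(rng_seed, stats::rpois(n_species, lambda))
  obs <- counts[counts > 0]
  attr(obs, "true_n") <- n_species
  attr(obs, "n_unobserved") <- n_species - length(obs)
  obs
}

#' Constant-richness world with heterogeneous spatial sampling
#'
#' The record-bias scenario: the species pool (true richness) is identical in
#' every bin, but the sampling window grows by the given multipliers, so raw
#' richness inherits a species-area trend that is pure sampling artefact.
#' Equal-spread standardization plus coverage-based subsampling should remove
#' it.
#'
#' @param cfg a [world_config()] (its trajectory is forced to constant).
#' @param spread_multipliers per-bin window scaling (default: linear doubling
#'   from 1 to 2 across the bins).
#' @param seed optional seed override.
#' @return a `fossil_world`.
#' @export
heterogeneous_sampling_scenario <- function(cfg = world_config(),
                                            spread_multipliers = NULL,
                                            seed = NULL) {
  if (is.null(spread_multipliers))
    spread_multipliers <- seq(1, 2, length.out = nrow(cfg$bins))
  stopifnot(length(spread_multipliers) == nrow(cfg$bins),
            all(spread_multipliers > 0))
  cfg$trajectory <- list(type = "constant")
  cfg$spread_multipliers <- spread_multipliers
  if (!is.null(seed)) cfg$seed <- seed
  generate_world(cfg)
}
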