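#' Pipeline configuration
#'
#' Bundles every parameter of the end-to-end workflow: input (an occurrence
#' CSV or a synthetic [world_config()]), cleaning filters, the time-bin
#' scheme, the spatial-standardization parameters and the richness-estimator
#' settings. Validation happens here, before any computation.
#'
#' @param input path to an occurrence CSV (PaleoDB dialect), or NULL when
#'   simulating.
#' @param world a [world_config()] to simulate from, or NULL when reading.
#' @param dialect column mapping for `input` (see [paleodb_dialect()]).
#' @param bins a `time_bins` data.frame or a CSV path; defaults to the
#'   world's bins (simulation) or the packaged Tr1--Pg2 scheme.
#' @param filter_flags flag categories to exclude during cleaning.
#' @param wastebasket_taxa taxon names to exclude.
#' @param cell_deg grid-cell size in degrees (default 1).
#' @param ceiling_km MST splitting ceiling (default 13000 km).
#' @param target_km equal-spread target summed MST length (default 3200 km).
#' @param tolerance acceptance band around the target (default 0.10).
#' @param n_reps replicate spatial samples per regional subtree (default 20).
#' @param min_km drop subtrees below this; default `target_km * (1 - tolerance)`.
#' @param sqs an [sqs_config()].
#' @param trips compute TRiPS estimates (default TRUE).
#' @param min_refs reference threshold for reportable estimates (default 20).
#' @param barriers data.frame (`from`, `to` cell ids) or CSV path of
#'   biogeographic barrier edges to cut, or NULL.
#' @param master_seed integer seed governing all randomness (default 1).
#' @param out_dir directory for output tables, or NULL to skip writing.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, world = NULL,
                            dialect = paleodb_dialect(), bins = NULL,
                            filter_flags = FLAG_FIELDS,
                            wastebasket_taxa = character(0),
                            cell_deg = 1, ceiling_km = 13000,
                            target_km = 3200, tolerance = 0.10, n_reps = 20,
                            min_km = NULL, sqs = sqs_config(), trips = TRUE,
                            min_refs = 20, barriers = NULL, master_seed = 1,
                            out_dir = NULL) {
  if (is.null(input) && is.null(world))
    stop("either 'input' (a CSV path) or 'world' (a world_config) is required",
         call. = FALSE)
  if (!is.null(input) && !file.exists(input))
    stop("input file not found: ", input, call. = FALSE)
  if (!is.null(world) && !inherits(world, "world_config"))
    stop("'world' must be a world_config()", call. = FALSE)
  if (is.character(bins)) {
    if (!file.exists(bins)) stop("bin scheme file not found: ", bins, call. = FALSE)
    bins <- read_time_bins(bins)
  }
  if (is.null(bins)) bins <- if (!is.null(world)) world$bins else default_time_bins()
  if (is.character(barriers)) {
    if (!file.exists(barriers)) stop("barrier file not found: ", barriers, call. = FALSE)
    barriers <- utils::read.csv(barriers, stringsAsFactors = FALSE,
                                colClasses = "character")
  }
  stopifnot(cell_deg > 0, ceiling_km > 0, target_km > 0,
            tolerance > 0, tolerance < 1, n_reps >= 1, min_refs >= 0,
            inherits(sqs, "sqs_config"))
  if (is.null(min_km)) min_km <- target_km * (1 - tolerance)
  stopifnot(min_km >= 0, ceiling_km > min_km)
  structure(list(input = input, world = world, dialect = dialect, bins = bins,
                 filter_flags = filter_flags,
                 wastebasket_taxa = wastebasket_taxa, cell_deg = cell_deg,
                 ceiling_km = ceiling_km, target_km = target_km,
                 tolerance = tolerance, n_reps = n_reps, min_km = min_km,
                 sqs = sqs, trips = trips, min_refs = min_refs,
                 barriers = barriers, master_seed = as.integer(master_seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config_echo(config), f, digits = NA, auto_unbox = TRUE)
  unname(tools::md5sum(f))
}

config_echo <- function(config) {
  list(input = config$input,
       simulated = !is.null(config$world),
       world_seed = if (!is.null(config$world)) config$world$seed else NULL,
       bins = as.data.frame(config$bins[, c("name", "start_ma", "end_ma")]),
       filter_flags = config$filter_flags,
       wastebasket_taxa = config$wastebasket_taxa,
       cell_deg = config$cell_deg, ceiling_km = config$ceiling_km,
       target_km = config$target_km, tolerance = config$tolerance,
       n_reps = config$n_reps, min_km = config$min_km,
       sqs = unclass(config$sqs), trips = config$trips,
       min_refs = config$min_refs, master_seed = config$master_seed)
}

#' Run the full spatial-standardization workflow
#'
#' Orchestrates the end-to-end analysis: read or simulate occurrences, clean
#' and time-bin them, grid each bin's collections to 1-degree cells, build
#' the global per-bin MST, split it into continental-scale subtrees, draw
#' replicate equal-spread samples, estimate richness (raw, SQS, TRiPS) for
#' both the unstandardized regional pools and the standardized samples, flag
#' estimates below the reference threshold, and fit log-link trend models to
#' every richness series. Deterministic given the configuration (including
#' `master_seed`); partial failures such as unsampleable subtrees or
#' degenerate estimates are recorded in the outputs, not fatal.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: `occurrences` (cleaned, binned),
#'   `cleaning_tally`, `spread` (per region x bin spread metrics),
#'   `manifest` (replicate manifest), `richness_unstandardized`,
#'   `richness_standardized`, `trends` (trend table), `fits` (the trend_fit
#'   objects), `config_hash`, `log` (stage-by-stage record). When
#'   `config$out_dir` is set the tables are also written there as CSV plus a
#'   JSON run log.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  # stage 1: load or simulate
  if (!is.null(config$world)) {
    world <- generate_world(config$world)
    occ <- world$occurrences
    log$source <- list(kind = "simulated", n_rows = nrow(occ))
  } else {
    occ <- read_occurrence_table(config$input, config$dialect)
    log$source <- list(kind = "file", path = config$input, n_rows = nrow(occ),
                       n_invalid = nrow(attr(occ, "errors")))
  }
  # stage 2: clean
  occ <- apply_taxon_filters(occ, flags = config$filter_flags,
                             wastebasket_taxa = config$wastebasket_taxa)
  tally <- attr(occ, "exclusion_tally")
  occ <- collapse_duplicates(occ)
  # stage 3: time bins
  occ <- assign_time_bins(occ, config$bins)
  log$cleaning <- list(tally = as.list(tally), n_after_collapse = nrow(occ),
                       n_unassigned = sum(is.na(occ$bin)))
  occ_binned <- occ[!is.na(occ$bin), , drop = FALSE]
  # seeds: one deterministic stream feeds every stochastic stage
  seed_pool <- with_local_seed(config$master_seed,
                               sample.int(.Machine$integer.max, 10000))
  seed_i <- 0L
  next_seed <- function() {
    seed_i <<- seed_i + 1L
    seed_pool[seed_i]
  }
  spread_rows <- list()
  manifest_rows <- list()
  unstd_pools <- list(); unstd_meta <- list()
  std_rows <- list()
  bins_used <- intersect(config$bins$name, unique(occ_binned$bin))
  for (bn in bins_used) {
    pool_b <- occ_binned[occ_binned$bin == bn, , drop = FALSE]
    colls <- unique(pool_b[, c("collection_id", "palaeolat", "palaeolon")])
    cells <- bin_to_grid(colls, cell_deg = config$cell_deg)
    if (nrow(cells) < 2) next
    mst <- build_mst(cells)
    subtrees <- split_global_mst(mst, ceiling_km = config$ceiling_km,
                                 min_km = config$min_km,
                                 target_km = config$target_km,
                                 tol = config$tolerance, bin = bn)
    if (!is.null(config$barriers))
      subtrees <- remove_barrier_edges(subtrees, config$barriers,
                                       min_km = config$min_km)
    for (st in subtrees) {
      region <- paste0(bn, "/", st$subtree_id)
      st_occ <- occurrences_of_cells(st$cells$cell_id, cells, pool_b)
      met <- spread_metrics(st$cells, mst = st)
      spread_rows[[length(spread_rows) + 1]] <- data.frame(
        region = region, bin = bn, summed_mst_km = met$summed_mst_km,
        convex_hull_km2 = met$convex_hull_km2, max_gcd_km = met$max_gcd_km,
        standard_distance_km = met$standard_distance_km,
        n_grid_cells = met$n_grid_cells, stringsAsFactors = FALSE)
      unstd_pools[[length(unstd_pools) + 1]] <- st_occ
      unstd_meta[[length(unstd_meta) + 1]] <- data.frame(
        region = region, bin = bn, mode = "unstandardized",
        stringsAsFactors = FALSE)
      samples <- replicate_spatial_samples(
        st, n_reps = config$n_reps, target_km = config$target_km,
        tol = config$tolerance, master_seed = next_seed())
      man <- attr(samples, "manifest")
      man <- cbind(data.frame(region = region, bin = bn,
                              stringsAsFactors = FALSE), man)
      manifest_rows[[length(manifest_rows) + 1]] <- man
      if (length(samples) == 0) next
      rep_pools <- lapply(samples, sample_occurrences, cells = cells,
                          occurrences = pool_b)
      rep_meta <- data.frame(
        region = region, bin = bn, mode = "standardized",
        replicate = vapply(samples, function(s) s$replicate_id, integer(1)),
        stringsAsFactors = FALSE)
      est <- estimate_all(rep_pools, rep_meta, cfg = config$sqs,
                          trips = config$trips, rng_seed = next_seed())
      std_rows[[length(std_rows) + 1]] <- est
    }
  }
  spread <- if (length(spread_rows)) do.call(rbind, spread_rows) else NULL
  manifest <- if (length(manifest_rows)) do.call(rbind, manifest_rows) else NULL
  unstd <- if (length(unstd_pools)) {
    estimate_all(unstd_pools, do.call(rbind, unstd_meta), cfg = config$sqs,
                 trips = config$trips, rng_seed = next_seed())
  } else NULL
  std_reps <- if (length(std_rows)) do.call(rbind, std_rows) else NULL
  std <- if (!is.null(std_reps)) aggregate_replicates(std_reps) else NULL
  if (!is.null(unstd)) unstd <- reference_threshold_filter(unstd, config$min_refs)
  if (!is.null(std)) std <- reference_threshold_filter(std, config$min_refs)
  mids <- stats::setNames(config$bins$midpoint_ma, config$bins$name)
  fits <- list()
  add_fit <- function(tab, col, label, family) {
    if (is.null(tab)) return()
    keep <- tab$reportable & is.finite(tab[[col]]) & tab[[col]] > 0
    pts <- data.frame(time_ma = mids[tab$bin[keep]], richness = tab[[col]][keep])
    f <- tryCatch(
      suppressWarnings(fit_trend(pts, family = family, series_label = label)),
      error = function(e) NULL)
    fits[[label]] <<- f
  }
  add_fit(unstd, "raw", "raw_unstandardized", "negative_binomial_log")
  add_fit(std, "raw", "raw_standardized", "negative_binomial_log")
  add_fit(unstd, "sqs_mean", "sqs_unstandardized", "gaussian_log")
  add_fit(std, "sqs_mean", "sqs_standardized", "gaussian_log")
  if (config$trips) {
    add_fit(unstd, "trips_hat", "trips_unstandardized", "gaussian_log")
    add_fit(std, "trips_hat", "trips_standardized", "gaussian_log")
  }
  trends <- trend_table(fits)
  log$pools <- list(n_bins_used = length(bins_used),
                    n_regions = if (is.null(unstd)) 0L else nrow(unstd),
                    n_accepted_samples =
                      if (is.null(manifest)) 0L else sum(manifest$accepted))
  out <- structure(list(occurrences = occ_binned, cleaning_tally = tally,
                        spread = spread, manifest = manifest,
                        richness_unstandardized = unstd,
                        richness_replicates = std_reps,
                        richness_standardized = std,
                        trends = trends, fits = fits,
                        config_hash = config_hash(config), log = log),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config)
  out
}

occurrences_of_cells <- function(cell_ids, cells, occurrences) {
  idx <- match(cell_ids, cells$cell_id)
  colls <- unlist(cells$member_collections[idx], use.names = FALSE)
  out <- occurrences[occurrences$collection_id %in% colls, , drop = FALSE]
  rownames(out) <- NULL
  out
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    if (!is.null(x))
      utils::write.csv(x, file.path(config$out_dir, name), row.names = FALSE)
  }
  write_occurrence_table(result$occurrences,
                         file.path(config$out_dir, "cleaned_occurrences.csv"))
  wr(result$spread, "spread_metrics.csv")
  wr(result$manifest, "replicate_manifest.csv")
  wr(result$richness_unstandardized, "richness_unstandardized.csv")
  wr(result$richness_replicates, "richness_replicates.csv")
  wr(result$richness_standardized, "richness_standardized.csv")
  wr(result$trends, "trend_table.csv")
  jsonlite::write_json(
    list(config = config_echo(config), config_hash = result$config_hash,
         log = result$log),
    file.path(config$out_dir, "run_log.json"),
    digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(config$out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Spatially standardized diversity analysis\n")
  cat("  occurrences (cleaned, binned):", nrow(x$occurrences), "\n")
  cat("  regional pools:",
      if (is.null(x$richness_unstandardized)) 0 else nrow(x$richness_unstandardized), "\n")
  cat("  accepted equal-spread samples:",
      if (is.null(x$manifest)) 0 else sum(x$manifest$accepted), "\n")
  if (!is.null(x$trends) && nrow(x$trends)) {
    cat("  trend fits:\n")
    print(x$trends[, c("series", "slope", "p_slope", "percent_increase")],
          row.names = FALSE)
  }
  invisible(x)
}
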