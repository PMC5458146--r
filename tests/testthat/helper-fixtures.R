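# shared fixture builders and independent oracles

# minimal occurrence data.frame in canonical columns
make_occ <- function(taxon, collection, reference = collection,
                     lat = 0.5, lon = 0.5, max_ma = 210, min_ma = 205,
                     rank = "species") {
  n <- max(length(taxon), length(collection))
  df <- data.frame(
    occurrence_id = sprintf("o%03d", seq_len(n)),
    collection_id = as.character(rep_len(collection, n)),
    taxon_name = rep_len(taxon, n),
    taxon_rank = rep_len(rank, n),
    reference_id = as.character(rep_len(reference, n)),
    palaeolat = rep_len(lat, n),
    palaeolon = rep_len(lon, n),
    interval_max_ma = rep_len(max_ma, n),
    interval_min_ma = rep_len(min_ma, n),
    stringsAsFactors = FALSE)
  for (f in c("marine", "flying", "ichno", "oo", "soft_tissue", "wastebasket"))
    df[[paste0("flag_", f)]] <- FALSE
  df
}

# grid_cells object from explicit integer cell indices
make_cells <- function(lat_idx, lon_idx) {
  cells <- data.frame(
    cell_id = paste(lat_idx, lon_idx, sep = ":"),
    lat_idx = lat_idx, lon_idx = lon_idx,
    centroid_lat = lat_idx + 0.5,
    centroid_lon = fossilspread::normalize_lon(lon_idx + 0.5),
    n_collections = 1L, stringsAsFactors = FALSE)
  cells$member_collections <- as.list(paste0("c", seq_along(lat_idx)))
  cells <- cells[order(cells$lat_idx, cells$lon_idx), ]
  rownames(cells) <- NULL
  class(cells) <- c("grid_cells", "data.frame")
  cells
}

# exhaustive minimum spanning tree total via Pruefer-sequence enumeration
# (all n^(n-2) labelled trees); independent of the package's Prim code
brute_force_mst_km <- function(cells) {
  n <- nrow(cells)
  d <- outer(seq_len(n), seq_len(n), function(i, j)
    fossilspread::great_circle_km(cells$centroid_lat[i], cells$centroid_lon[i],
                                  cells$centroid_lat[j], cells$centroid_lon[j]))
  if (n == 1) return(0)
  if (n == 2) return(d[1, 2])
  tree_len_from_pruefer <- function(pr) {
    degree <- rep(1L, n)
    for (v in pr) degree[v] <- degree[v] + 1L
    total <- 0
    pr <- c(pr)
    for (v in pr) {
      leaf <- which(degree == 1L)[1]
      total <- total + d[leaf, v]
      degree[leaf] <- 0L
      degree[v] <- degree[v] - 1L
    }
    last <- which(degree == 1L)
    total + d[last[1], last[2]]
  }
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  min(apply(seqs, 1, tree_len_from_pruefer))
}

# expectation of SQS richness by exhaustive enumeration of collection orders
sqs_exhaustive_expectation <- function(pool, quorum,
                                       singleton_rule = "by_collection") {
  pool <- fossilspread::collapse_duplicates(pool)
  u <- fossilspread::goods_u(pool, singleton_rule = singleton_rule,
                             collapse = FALSE)
  share <- table(pool$taxon_name) / nrow(pool)
  colls <- unique(pool$collection_id)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  richness <- vapply(perms(colls), function(ord) {
    seen <- character(0)
    cov <- 0
    for (cid in ord) {
      tx <- pool$taxon_name[pool$collection_id == cid]
      new <- setdiff(tx, seen)
      seen <- c(seen, new)
      cov <- cov + sum(share[new])
      if (u * cov >= quorum - 1e-12) break
    }
    length(seen)
  }, numeric(1))
  mean(richness)
}

# bisection oracle for the zero-truncated-Poisson mean equation
ztp_bisection_oracle <- function(target_mean, lo = 1e-12, hi = 100) {
  g <- function(l) l / (1 - exp(-l))
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) < target_mean) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# small heterogeneous-sampling analysis used by several tests: returns the
# trend table, manifest and spread table of one synthetic record-bias world
run_record_bias_world <- function(seed, n_reps = 10, n_trials = 50) {
  w <- fossilspread::heterogeneous_sampling_scenario(
    fossilspread::world_config(seed = seed))
  cfg <- fossilspread::pipeline_config(
    world = w$config, n_reps = n_reps,
    sqs = fossilspread::sqs_config(n_trials = n_trials), master_seed = seed)
  fossilspread::run_pipeline(cfg)
}
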