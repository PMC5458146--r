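#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0 km (the mean Earth radius,
#' under which one degree of latitude spans ~111.19 km). Vectorised over
#' coordinate vectors, recycling as usual.
#'
#' @param lat1,lon1 coordinates of the first point(s), decimal degrees.
#' @param lat2,lon2 coordinates of the second point(s), decimal degrees.
#' @return numeric vector of distances in km.
#' @examples
#' great_circle_km(0, 0, 1, 0)   # ~111.19 km, one degree of latitude
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad
  phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

EARTH_RADIUS_KM <- 6371.0

check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    stop("non-finite coordinate", call. = FALSE)
  if (any(lat < -90 | lat > 90))
    stop("palaeolatitude outside [-90, 90]", call. = FALSE)
  if (any(lon <= -180 | lon > 180))
    stop("palaeolongitude outside (-180, 180]", call. = FALSE)
  invisible(TRUE)
}

#' Normalize longitudes into (-180, 180]
#' @param lon numeric vector of longitudes in degrees.
#' @return normalized longitudes.
#' @export
normalize_lon <- function(lon) {
  out <- ((lon + 180) %% 360) - 180
  out[out == -180] <- 180
  out
}

# Pairwise great-circle distance matrix between rows of (lat, lon)
gc_dist_matrix <- function(lat, lon) {
  n <- length(lat)
  to_rad <- pi / 180
  phi <- lat * to_rad
  lam <- lon * to_rad
  # unit vectors; chord -> central angle, numerically stable enough here
  x <- cos(phi) * cos(lam)
  y <- cos(phi) * sin(lam)
  z <- sin(phi)
  m <- cbind(x, y, z)
  dot <- tcrossprod(m)
  dot <- pmin(pmax(dot, -1), 1)
  d <- EARTH_RADIUS_KM * acos(dot)
  diag(d) <- 0
  d
}

#' Bin collections into 1-degree grid cells
#'
#' Assigns each collection's palaeocoordinates to an equal-angle grid cell
#' (index = floor(coordinate / cell_deg), anchored at 0 degrees) and collapses
#' collections to occupied-cell centroids. This removes the summed
#' contributions of small-scale inter-locality distances from spread metrics.
#'
#' @param collections data.frame with columns `collection_id`, `palaeolat`,
#'   `palaeolon` (one row per collection; duplicated ids are collapsed).
#' @param cell_deg cell size in degrees (default 1).
#' @return data.frame of class `grid_cells`, one row per occupied cell:
#'   `cell_id`, `lat_idx`, `lon_idx`, `centroid_lat`, `centroid_lon`,
#'   `n_collections`, and list-column `member_collections`.
#' @export
bin_to_grid <- function(collections, cell_deg = 1) {
  stopifnot(is.data.frame(collections),
            all(c("collection_id", "palaeolat", "palaeolon") %in% names(collections)))
  collections <- collections[!duplicated(collections$collection_id), , drop = FALSE]
  lat <- collections$palaeolat
  lon <- normalize_lon(collections$palaeolon)
  check_coords(lat, lon)
  lat_idx <- floor(lat / cell_deg)
  lon_idx <- floor(lon / cell_deg)
  # points exactly on the upper domain edge fall into the topmost cell
  lat_idx <- pmin(lat_idx, ceiling(90 / cell_deg) - 1)
  lon_idx <- pmin(lon_idx, ceiling(180 / cell_deg) - 1)
  key <- paste(lat_idx, lon_idx, sep = ":")
  ord <- order(lat_idx, lon_idx)
  ukey <- unique(key[ord])
  idx <- match(ukey, key)
  cells <- data.frame(
    cell_id = ukey,
    lat_idx = lat_idx[idx],
    lon_idx = lon_idx[idx],
    centroid_lat = (lat_idx[idx] + 0.5) * cell_deg,
    centroid_lon = normalize_lon((lon_idx[idx] + 0.5) * cell_deg),
    stringsAsFactors = FALSE
  )
  members <- split(as.character(collections$collection_id), factor(key, levels = ukey))
  cells$n_collections <- vapply(members, length, integer(1))
  cells$member_collections <- unname(members)
  attr(cells, "cell_deg") <- cell_deg
  class(cells) <- c("grid_cells", "data.frame")
  cells
}

#' Minimum spanning tree over grid-cell centroids
#'
#' Exact MST of the complete graph on occupied grid cells with great-circle
#' edge weights. Ties between equal-weight candidate edges are broken in
#' favour of the lexicographically smaller (by grid index) cell pair, so the
#' edge set is deterministic.
#'
#' @param cells a `grid_cells` data.frame (or any data.frame with `cell_id`,
#'   `centroid_lat`, `centroid_lon`).
#' @return list of class `spatial_mst` with `cells`, `edges` (data.frame
#'   `from`, `to`, `km`) and `total_km` (the summed MST length).
#' @export
build_mst <- function(cells) {
  stopifnot(is.data.frame(cells), nrow(cells) >= 1)
  if (!is.null(cells$lat_idx)) {
    cells <- cells[order(cells$lat_idx, cells$lon_idx), , drop = FALSE]
  } else {
    cells <- cells[order(cells$cell_id), , drop = FALSE]
  }
  n <- nrow(cells)
  if (n == 1) {
    out <- list(cells = cells,
                edges = data.frame(from = character(0), to = character(0),
                                   km = numeric(0), stringsAsFactors = FALSE),
                total_km = 0)
    class(out) <- "spatial_mst"
    return(out)
  }
  d <- gc_dist_matrix(cells$centroid_lat, cells$centroid_lon)
  # Prim's algorithm; scanning vertices in sorted-id order means the first
  # minimum found is the lexicographic tie-break winner
  in_tree <- rep(FALSE, n)
  in_tree[1] <- TRUE
  best_dist <- d[1, ]
  best_from <- rep(1L, n)
  from <- integer(n - 1)
  to <- integer(n - 1)
  km <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best_dist[cand])]
    from[k] <- best_from[j]
    to[k] <- j
    km[k] <- best_dist[j]
    in_tree[j] <- TRUE
    upd <- !in_tree & d[j, ] < best_dist
    best_dist[upd] <- d[j, upd]
    best_from[upd] <- j
  }
  a <- pmin(from, to)
  b <- pmax(from, to)
  edges <- data.frame(from = cells$cell_id[a], to = cells$cell_id[b],
                      km = km, stringsAsFactors = FALSE)
  edges <- edges[order(a, b), , drop = FALSE]
  rownames(edges) <- NULL
  out <- list(cells = cells, edges = edges, total_km = sum(km))
  class(out) <- "spatial_mst"
  out
}

#' @export
print.spatial_mst <- function(x, ...) {
  cat("Spatial MST:", nrow(x$cells), "grid cells,",
      nrow(x$edges), "edges, summed length",
      format(round(x$total_km, 1), big.mark = ","), "km\n")
  invisible(x)
}

# geographic mean point: normalized mean of unit vectors (robust near the
# antimeridian, unlike averaging raw lat/lon)
mean_point <- function(lat, lon) {
  to_rad <- pi / 180
  phi <- lat * to_rad
  lam <- lon * to_rad
  v <- c(mean(cos(phi) * cos(lam)), mean(cos(phi) * sin(lam)), mean(sin(phi)))
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) return(c(lat = 0, lon = 0))  # degenerate: points balance out
  v <- v / nv
  c(lat = asin(pmin(pmax(v[3], -1), 1)) / to_rad,
    lon = atan2(v[2], v[1]) / to_rad)
}

# Lambert azimuthal equal-area projection about (lat0, lon0); returns km
laea_project <- function(lat, lon, lat0, lon0) {
  to_rad <- pi / 180
  phi <- lat * to_rad; lam <- lon * to_rad
  phi0 <- lat0 * to_rad; lam0 <- lon0 * to_rad
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  denom <- pmax(denom, 1e-12)
  k <- sqrt(2 / denom)
  cbind(x = EARTH_RADIUS_KM * k * cos(phi) * sin(lam - lam0),
        y = EARTH_RADIUS_KM * k * (cos(phi0) * sin(phi) -
                                     sin(phi0) * cos(phi) * cos(lam - lam0)))
}

shoelace_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Palaeogeographic spread metrics of a set of grid cells
#'
#' Computes the five spread metrics used to describe the geographic sampling
#' universe of a regional pool: summed MST length, convex-hull area (on a
#' Lambert azimuthal equal-area projection about the geographic mean point),
#' maximum great-circle distance, standard distance (root-mean-square
#' great-circle distance of cells from their geographic mean point) and the
#' number of occupied grid cells.
#'
#' @param cells a `grid_cells` data.frame.
#' @param mst optionally a precomputed `spatial_mst` for these cells.
#' @return named list with `summed_mst_km`, `convex_hull_km2`, `max_gcd_km`,
#'   `standard_distance_km`, `n_grid_cells`; attribute `degenerate_hull` is
#'   TRUE when fewer than 3 non-collinear cells exist (hull reported as 0).
#' @export
spread_metrics <- function(cells, mst = NULL) {
  stopifnot(is.data.frame(cells), nrow(cells) >= 1)
  n <- nrow(cells)
  if (is.null(mst)) mst <- build_mst(cells)
  lat <- cells$centroid_lat
  lon <- cells$centroid_lon
  if (n == 1) {
    out <- list(summed_mst_km = 0, convex_hull_km2 = 0, max_gcd_km = 0,
                standard_distance_km = 0, n_grid_cells = 1L)
    attr(out, "degenerate_hull") <- TRUE
    return(out)
  }
  d <- gc_dist_matrix(lat, lon)
  ctr <- mean_point(lat, lon)
  sdist <- sqrt(mean(great_circle_km(lat, lon, ctr["lat"], ctr["lon"])^2))
  xy <- laea_project(lat, lon, ctr["lat"], ctr["lon"])
  hull_idx <- grDevices::chull(xy)
  degenerate <- length(hull_idx) < 3
  hull_area <- if (degenerate) 0 else shoelace_area(xy[hull_idx, , drop = FALSE])
  if (!degenerate && hull_area < 1e-9) {
    degenerate <- TRUE
    hull_area <- 0
  }
  out <- list(summed_mst_km = mst$total_km,
              convex_hull_km2 = hull_area,
              max_gcd_km = max(d),
              standard_distance_km = sdist,
              n_grid_cells = n)
  attr(out, "degenerate_hull") <- degenerate
  out
}

#' Pearson correlations among spread metrics across pools
#'
#' @param pool_metrics data.frame with one row per regional pool and one
#'   column per spread metric (e.g. rows of [spread_metrics()] outputs).
#' @return correlation matrix; entries for metrics with zero variance are NA.
#' @export
metric_correlations <- function(pool_metrics) {
  stopifnot(is.data.frame(pool_metrics), nrow(pool_metrics) >= 3)
  m <- as.matrix(pool_metrics[vapply(pool_metrics, is.numeric, logical(1))])
  const <- apply(m, 2, function(v) stats::sd(v) == 0 || !is.finite(stats::sd(v)))
  r <- suppressWarnings(stats::cor(m, method = "pearson"))
  r[const, ] <- NA
  r[, const] <- NA
  diag(r) <- ifelse(const, NA, 1)
  r
}
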