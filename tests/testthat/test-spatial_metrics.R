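test_that("great-circle distance reproduces analytic values", {
  expect_equal(great_circle_km(0, 0, 0, 0), 0)
  # one degree of latitude ~111.19 km on the 6371-km sphere
  expect_equal(great_circle_km(0, 0, 1, 0), pi * 6371 / 180, tolerance = 1e-10)
  # antipodal points: half the circumference
  expect_equal(great_circle_km(0, 0, 0, 180), pi * 6371, tolerance = 1e-6)
  expect_error(great_circle_km(95, 0, 0, 0), "palaeolatitude")
})

test_that("great-circle distance is symmetric, triangle-inequal, and matches geosphere", {
  set.seed(11)
  lat <- runif(60, -89, 89)
  lon <- runif(60, -179, 179)
  i <- 1:20; j <- 21:40; k <- 41:60
  dij <- great_circle_km(lat[i], lon[i], lat[j], lon[j])
  dji <- great_circle_km(lat[j], lon[j], lat[i], lon[i])
  expect_equal(dij, dji)
  dik <- great_circle_km(lat[i], lon[i], lat[k], lon[k])
  dkj <- great_circle_km(lat[k], lon[k], lat[j], lon[j])
  expect_true(all(dij <= dik + dkj + 1e-9))
  skip_if_not_installed("geosphere")
  ref <- geosphere::distHaversine(cbind(lon[i], lat[i]), cbind(lon[j], lat[j]),
                                  r = 6371)
  expect_equal(dij, ref, tolerance = 1e-9)
})

test_that("grid binning floors coordinates into 1-degree cells", {
  co <- data.frame(collection_id = as.character(1:5),
                   palaeolat = rep(12.3, 5), palaeolon = rep(45.6, 5))
  cells <- bin_to_grid(co)
  expect_equal(nrow(cells), 1)
  expect_equal(cells$centroid_lat, 12.5)
  expect_equal(cells$centroid_lon, 45.5)
  expect_equal(cells$n_collections, 5L)

  co2 <- data.frame(collection_id = c("a", "b"),
                    palaeolat = c(0.2, 0.8), palaeolon = c(0.2, 0.8))
  expect_equal(nrow(bin_to_grid(co2)), 1)

  set.seed(3)
  co3 <- data.frame(collection_id = as.character(1:200),
                    palaeolat = runif(200, -89, 89),
                    palaeolon = runif(200, -179, 179))
  cells3 <- bin_to_grid(co3)
  membership <- rep(cells3$cell_id, lengths(cells3$member_collections))
  got <- membership[match(co3$collection_id,
                          unlist(cells3$member_collections))]
  want <- paste(floor(co3$palaeolat), floor(co3$palaeolon), sep = ":")
  expect_identical(got, want)
})

test_that("occupied-cell count is invariant to within-cell jitter", {
  set.seed(9)
  base_lat <- sample(-30:30, 25, replace = TRUE) + 0.5
  base_lon <- sample(-60:60, 25, replace = TRUE) + 0.5
  co <- data.frame(collection_id = as.character(1:25),
                   palaeolat = base_lat, palaeolon = base_lon)
  n0 <- nrow(bin_to_grid(co))
  for (r in 1:5) {
    co$palaeolat <- base_lat + runif(25, -0.49, 0.49)
    co$palaeolon <- base_lon + runif(25, -0.49, 0.49)
    expect_equal(nrow(bin_to_grid(co)), n0)
  }
})

test_that("MST handles degenerate sizes and a collinear chain", {
  one <- make_cells(0, 0)
  m1 <- build_mst(one)
  expect_equal(nrow(m1$edges), 0)
  expect_equal(m1$total_km, 0)

  two <- make_cells(c(0, 5), c(0, 3))
  m2 <- build_mst(two)
  expect_equal(nrow(m2$edges), 1)
  expect_equal(m2$total_km,
               great_circle_km(0.5, 0.5, 5.5, 3.5))

  chain <- make_cells(c(0, 0, 0), c(0, 1, 2))
  m3 <- build_mst(chain)
  step <- great_circle_km(0.5, 0.5, 0.5, 1.5)
  expect_equal(m3$total_km, 2 * step, tolerance = 1e-9)
  expect_equal(m3$total_km, brute_force_mst_km(chain), tolerance = 1e-9)
})

test_that("MST equals the exhaustive spanning-tree minimum for n <= 7", {
  set.seed(21)
  for (n in c(4, 5, 6, 7)) {
    for (rep in 1:3) {
      cells <- make_cells(sample(-40:40, n), sample(-80:80, n))
      m <- build_mst(cells)
      expect_equal(nrow(m$edges), n - 1)
      expect_equal(m$total_km, brute_force_mst_km(cells), tolerance = 1e-8)
    }
  }
})

test_that("spread metrics match pairwise oracles and degenerate rules", {
  one <- make_cells(10, 10)
  s1 <- spread_metrics(one)
  expect_equal(unlist(s1[c("summed_mst_km", "convex_hull_km2", "max_gcd_km",
                           "standard_distance_km")]),
               c(summed_mst_km = 0, convex_hull_km2 = 0, max_gcd_km = 0,
                 standard_distance_km = 0))
  expect_true(attr(s1, "degenerate_hull"))

  two <- make_cells(c(-40, 40), c(-90, 80))
  s2 <- spread_metrics(two)
  expect_equal(s2$max_gcd_km, s2$summed_mst_km)

  set.seed(5)
  g <- expand.grid(lat = -20:20, lon = -50:50)
  idx <- sample(nrow(g), 50)
  cl <- make_cells(g$lat[idx], g$lon[idx])
  s <- spread_metrics(cl)
  d <- outer(seq_len(nrow(cl)), seq_len(nrow(cl)), function(i, j)
    great_circle_km(cl$centroid_lat[i], cl$centroid_lon[i],
                    cl$centroid_lat[j], cl$centroid_lon[j]))
  expect_equal(s$max_gcd_km, max(d))
  expect_equal(s$n_grid_cells, nrow(cl))
  expect_gt(s$convex_hull_km2, 0)

  # cells along one meridian (a great circle): degenerate hull, zero area
  lin <- make_cells(c(0, 2, 4, 6), rep(0, 4))
  slin <- spread_metrics(lin)
  expect_true(attr(slin, "degenerate_hull"))
  expect_equal(slin$convex_hull_km2, 0)
})

test_that("summed MST length bounds the endpoints of its longest path", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(5:12, 1)
    cells <- make_cells(sample(-40:40, n), sample(-80:80, n))
    m <- build_mst(cells)
    # distance between any two cells is <= total tree length (path bound)
    d <- outer(seq_len(n), seq_len(n), function(i, j)
      great_circle_km(cells$centroid_lat[i], cells$centroid_lon[i],
                      cells$centroid_lat[j], cells$centroid_lon[j]))
    # the tree connects the two farthest-apart cells, and every tree path is
    # at least as long as the straight-line (great-circle) distance
    expect_gte(m$total_km + 1e-9, max(d))
  }
})

test_that("metric correlations follow the textbook Pearson formula", {
  # pools whose metrics all scale together correlate perfectly
  scaled <- data.frame(summed_mst_km = c(1, 2, 3, 4) * 1000,
                       max_gcd_km = c(1, 2, 3, 4) * 400,
                       n_grid_cells = c(1, 2, 3, 4) * 7)
  r <- metric_correlations(scaled)
  expect_true(all(abs(r - 1) < 1e-12))

  set.seed(13)
  pools <- lapply(1:100, function(i) {
    n <- sample(4:25, 1)
    make_cells(sample(-60:60, n), sample(-120:120, n))
  })
  met <- do.call(rbind, lapply(pools, function(p)
    as.data.frame(spread_metrics(p)[c("summed_mst_km", "convex_hull_km2",
                                      "max_gcd_km", "standard_distance_km",
                                      "n_grid_cells")])))
  r2 <- metric_correlations(met)
  pearson <- function(x, y) {
    xm <- x - mean(x); ym <- y - mean(y)
    sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  }
  expect_equal(r2["summed_mst_km", "max_gcd_km"],
               pearson(met$summed_mst_km, met$max_gcd_km), tolerance = 1e-12)
  expect_equal(r2["convex_hull_km2", "n_grid_cells"],
               pearson(met$convex_hull_km2, met$n_grid_cells), tolerance = 1e-12)
  # a constant metric has no defined correlation
  met$constant <- 5
  r3 <- metric_correlations(met)
  expect_true(all(is.na(r3["constant", ])))
})
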