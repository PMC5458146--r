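# two tight clusters of equatorial cells joined by one long longitudinal gap
two_cluster_mst <- function(gap_deg = 85) {
  cells <- make_cells(rep(0, 12), c(0:5, gap_deg + 0:5))
  build_mst(cells)
}

test_that("splitting removes long branches until components sit below the ceiling", {
  small <- build_mst(make_cells(rep(0, 5), 0:4))  # ~445 km chain
  out <- split_global_mst(small, ceiling_km = 13000, min_km = 100)
  expect_length(out, 1)
  expect_equal(out[[1]]$total_km, small$total_km)

  big <- two_cluster_mst()  # two ~556 km chains + one ~8,890 km bridge
  expect_gt(big$total_km, 9000)
  out2 <- split_global_mst(big, ceiling_km = 9000, min_km = 400)
  expect_length(out2, 2)
  expect_true(all(vapply(out2, function(s) s$total_km, numeric(1)) < 9000))
  # the removed edge is the unique longest one: each side keeps its chain
  expect_equal(sort(vapply(out2, function(s) nrow(s$cells), numeric(1))),
               c(6, 6))

  # min_km drops both remaining subtrees
  out3 <- split_global_mst(big, ceiling_km = 9000, min_km = 600)
  expect_length(out3, 0)
})

test_that("no split component ever reaches the ceiling", {
  set.seed(17)
  for (rep in 1:5) {
    g <- expand.grid(lat = -30:30, lon = -60:60)
    idx <- sample(nrow(g), 40)
    mst <- build_mst(make_cells(g$lat[idx], g$lon[idx]))
    parts <- split_global_mst(mst, ceiling_km = 4000, min_km = 0)
    expect_true(all(vapply(parts, function(s) s$total_km, numeric(1)) < 4000))
  }
})

test_that("barrier edges re-split subtrees and unmatched barriers warn", {
  big <- two_cluster_mst()
  subtrees <- split_global_mst(big, ceiling_km = 1e6, min_km = 0)
  expect_length(subtrees, 1)
  expect_identical(remove_barrier_edges(subtrees,
                                        data.frame(from = character(0),
                                                   to = character(0)),
                                        min_km = 0),
                   subtrees)
  # cutting the bridge splits the tree in two
  bridge <- subtrees[[1]]$edges[which.max(subtrees[[1]]$edges$km), ]
  cut <- remove_barrier_edges(subtrees, bridge[, c("from", "to")], min_km = 400)
  expect_length(cut, 2)
  # a min_km above the fragment size drops it
  cut2 <- remove_barrier_edges(subtrees, bridge[, c("from", "to")], min_km = 600)
  expect_length(cut2, 0)
  expect_warning(
    remove_barrier_edges(subtrees, data.frame(from = "99:99", to = "98:98"),
                         min_km = 0),
    "no edge")
})

test_that("growth stops nearest the target and respects the band", {
  # equatorial chain: 41 cells, 40 edges of ~111.18 km
  chain <- build_mst(make_cells(rep(0, 41), 0:40))
  subtree <- split_global_mst(chain, ceiling_km = 1e6, min_km = 0)[[1]]
  step <- great_circle_km(0.5, 0.5, 0.5, 1.5)

  s <- grow_spatial_sample(subtree, target_km = 3200, tol = 0.10,
                           start_cell = "0:0")
  expect_true(s$accepted)
  # from one end, 28 edges give 3,113 km and 29 give 3,225; 29 is closer
  expect_equal(length(s$cells), 30)
  expect_equal(s$induced_mst_km, 29 * step, tolerance = 1e-9)

  # induced length is monotone non-decreasing during growth
  expect_true(all(diff(s$growth_km) >= 0))

  # the sample is a connected subtree of the parent MST
  sub_cells <- s$cells
  sub_edges <- subtree$edges[subtree$edges$from %in% sub_cells &
                               subtree$edges$to %in% sub_cells, ]
  expect_equal(nrow(sub_edges), length(sub_cells) - 1)

  # a subtree equal to the target is returned whole
  exact <- split_global_mst(chain, ceiling_km = 1e6, min_km = 0)[[1]]
  s2 <- grow_spatial_sample(exact, target_km = exact$total_km, tol = 0.10,
                            start_cell = "0:20")
  expect_true(s2$accepted)
  expect_equal(length(s2$cells), 41)
  expect_equal(s2$induced_mst_km, exact$total_km)

  # an infeasible subtree is rejected with a reason
  short <- build_mst(make_cells(rep(0, 23), 0:22))  # ~2,446 km
  short_sub <- split_global_mst(short, ceiling_km = 1e6, min_km = 0)[[1]]
  r <- grow_spatial_sample(short_sub, target_km = 3200, tol = 0.10)
  expect_false(r$accepted)
  expect_match(r$reason, "below target band")
})

test_that("replicate draws are reproducible and tight around the target", {
  chain <- build_mst(make_cells(rep(0, 41), 0:40))
  subtree <- split_global_mst(chain, ceiling_km = 1e6, min_km = 0)[[1]]
  a <- replicate_spatial_samples(subtree, n_reps = 20, target_km = 3200,
                                 tol = 0.10, master_seed = 99)
  b <- replicate_spatial_samples(subtree, n_reps = 20, target_km = 3200,
                                 tol = 0.10, master_seed = 99)
  expect_identical(attr(a, "manifest"), attr(b, "manifest"))
  expect_identical(lapply(a, `[[`, "cells"), lapply(b, `[[`, "cells"))
  man <- attr(a, "manifest")
  expect_true(all(man$accepted))
  expect_true(all(abs(man$induced_mst_km - 3200) <= 3200 * 0.10 + 1e-9))

  # a subtree exactly at the target yields identical full-subtree samples
  exact <- split_global_mst(chain, ceiling_km = 1e6, min_km = 0)[[1]]
  tgt <- exact$total_km
  full <- replicate_spatial_samples(exact, n_reps = 20, target_km = tgt,
                                    tol = 0.10, master_seed = 5)
  expect_length(full, 20)
  expect_equal(vapply(full, function(s) s$induced_mst_km, numeric(1)),
               rep(tgt, 20), tolerance = 1e-9)
  expect_true(all(vapply(full, function(s) length(s$cells), numeric(1)) == 41))

  # far-too-small subtree: unsampleable, not fatal
  tiny <- split_global_mst(build_mst(make_cells(rep(0, 3), 0:2)),
                           ceiling_km = 1e6, min_km = 0)[[1]]
  none <- replicate_spatial_samples(tiny, n_reps = 5, target_km = 3200,
                                    tol = 0.10, master_seed = 1)
  expect_length(none, 0)
  expect_true(attr(none, "unsampleable"))
})

test_that("accepted-sample spread varies far less than unstandardized pools", {
  set.seed(4)
  # heterogeneous world: per-bin pool spreads differ several-fold
  out <- run_record_bias_world(seed = 910, n_reps = 10, n_trials = 10)
  acc <- out$manifest$induced_mst_km[out$manifest$accepted]
  cv_std <- sd(acc) / mean(acc)
  cv_unstd <- sd(out$spread$summed_mst_km) / mean(out$spread$summed_mst_km)
  expect_lte(cv_std, 0.06)
  expect_gte(cv_unstd / cv_std, 3)
})

test_that("sample occurrences are exactly those of the member cells", {
  w <- generate_world(world_config(seed = 8, bins = synthetic_time_bins(1)))
  occ <- collapse_duplicates(w$occurrences)
  colls <- unique(occ[, c("collection_id", "palaeolat", "palaeolon")])
  cells <- bin_to_grid(colls)
  mst <- build_mst(cells)
  subtree <- split_global_mst(mst, ceiling_km = 1e6, min_km = 0)[[1]]
  s <- grow_spatial_sample(subtree, target_km = 2000, tol = 0.10,
                           rng_seed = 2)
  expect_true(s$accepted)
  got <- sample_occurrences(s, cells, occ)
  in_cells <- paste(floor(occ$palaeolat), floor(occ$palaeolon), sep = ":") %in%
    s$cells
  expect_setequal(got$occurrence_id, occ$occurrence_id[in_cells])
})
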