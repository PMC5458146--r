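test_that("reading validates rows and preserves order", {
  hdr <- "occurrence_no,collection_no,accepted_name,accepted_rank,reference_no,paleolat,paleolng,max_ma,min_ma"
  f <- withr::local_tempfile(fileext = ".csv")

  writeLines(hdr, f)
  empty <- read_occurrence_table(f)
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(attr(empty, "errors")), 0)

  writeLines(c(hdr,
               "1,10,Aa bb,species,100,10.5,20.5,210,205",
               "2,11,Cc dd,species,101,95,20.5,210,205",
               "3,12,Ee ff,genus,102,-10.5,-20.5,220,214"), f)
  recs <- read_occurrence_table(f)
  expect_equal(nrow(recs), 2)
  expect_equal(recs$occurrence_id, c("1", "3"))
  errs <- attr(recs, "errors")
  expect_equal(errs$row, 2L)
  expect_equal(errs$field, "palaeolat")

  # missing mandatory column is a configuration error
  writeLines("occurrence_no,collection_no", f)
  expect_error(read_occurrence_table(f), "missing")
})

test_that("a written synthetic table round-trips exactly", {
  w <- generate_world(world_config(seed = 42,
                                   bins = synthetic_time_bins(2),
                                   n_collections = 30))
  occ <- utils::head(w$occurrences, 1000)
  f <- withr::local_tempfile(fileext = ".csv")
  write_occurrence_table(occ, f)
  back <- read_occurrence_table(f)
  expect_equal(nrow(attr(back, "errors")), 0)
  attr(back, "errors") <- NULL
  expect_identical(back[, c("occurrence_id", "collection_id", "taxon_name",
                            "reference_id")],
                   occ[, c("occurrence_id", "collection_id", "taxon_name",
                           "reference_id")])
  for (col in c("palaeolat", "palaeolon", "interval_max_ma", "interval_min_ma"))
    expect_equal(back[[col]], occ[[col]])
})

test_that("taxon filters remove flagged and indeterminate records with a tally", {
  clean <- make_occ(paste0("sp", 1:10), paste0("c", 1:10))
  kept <- apply_taxon_filters(clean)
  expect_equal(nrow(kept), 10)
  expect_true(all(attr(kept, "exclusion_tally") == 0))

  flagged <- make_occ(paste0("sp", 1:5), paste0("c", 1:5))
  for (i in seq_len(5))
    flagged[[paste0("flag_", c("marine", "flying", "ichno", "oo", "soft_tissue")[i])]][i] <- TRUE
  expect_equal(nrow(apply_taxon_filters(flagged)), 0)

  mixed <- make_occ(paste0("sp", 1:20), paste0("c", 1:20))
  mixed$flag_ichno[1:4] <- TRUE
  mixed$taxon_rank[5:7] <- "indeterminate"
  res <- apply_taxon_filters(mixed)
  expect_equal(nrow(res), 13)
  tly <- attr(res, "exclusion_tally")
  expect_equal(unname(tly["ichno"]), 4L)
  expect_equal(unname(tly["indeterminate"]), 3L)

  # idempotence
  twice <- apply_taxon_filters(res)
  attr(twice, "exclusion_tally") <- NULL
  attr(res, "exclusion_tally") <- NULL
  expect_identical(twice, res)

  # wastebasket names are a user-supplied list
  wb <- apply_taxon_filters(mixed, wastebasket_taxa = c("sp10", "sp11"))
  expect_false(any(wb$taxon_name %in% c("sp10", "sp11")))
})

test_that("time-bin assignment uses closed full containment", {
  bins <- time_bins(c("A", "B"), c(237, 201.3), c(201.3, 190))
  r <- make_occ("x", "c1", max_ma = 210, min_ma = 205)
  expect_equal(assign_time_bins(r, bins)$bin, "A")
  # an interval spanning the 201.3 Ma boundary belongs to no bin
  r2 <- make_occ("x", "c1", max_ma = 202, min_ma = 199)
  expect_true(is.na(assign_time_bins(r2, bins)$bin))
  # ages exactly on the boundary count as inside
  r3 <- make_occ("x", "c1", max_ma = 237, min_ma = 201.3)
  expect_equal(assign_time_bins(r3, bins)$bin, "A")
  expect_error(time_bins(c("A", "B"), c(237, 210), c(201.3, 190)), "overlap")
})

test_that("bin assignment matches brute-force containment and partitions records", {
  set.seed(7)
  bins <- synthetic_time_bins(6, oldest_ma = 250, duration_myr = 9)
  mx <- runif(100, 196, 252)
  mn <- mx - runif(100, 0, 12)
  recs <- make_occ(paste0("sp", 1:100), paste0("c", 1:100))
  recs$interval_max_ma <- mx
  recs$interval_min_ma <- mn
  got <- assign_time_bins(recs, bins)$bin
  want <- vapply(seq_len(100), function(i) {
    hit <- which(mx[i] <= bins$start_ma & mn[i] >= bins$end_ma)
    if (length(hit)) bins$name[hit[1]] else NA_character_
  }, character(1))
  expect_identical(got, want)
  # each assigned record matches exactly one bin
  n_hits <- vapply(seq_len(100), function(i)
    sum(mx[i] <= bins$start_ma & mn[i] >= bins$end_ma), numeric(1))
  expect_true(all(n_hits <= 1))
})

test_that("pool diagnostics match direct counts and ignore record order", {
  one <- make_occ("sp1", c("c1", "c1", "c2", "c2", "c3"))
  d1 <- pool_diagnostics(one, collapse = FALSE)
  expect_equal(d1$raw_richness, 1)
  expect_equal(d1$dominance, 1.0)

  singletons <- make_occ(paste0("sp", 1:10), paste0("c", 1:10))
  expect_equal(pool_diagnostics(singletons)$goods_u, 0)

  # A x4, B x3, C x2 in multiple collections; D once
  pool <- make_occ(c(rep("A", 4), rep("B", 3), rep("C", 2), "D"),
                   c("c1", "c2", "c3", "c4", "c1", "c2", "c3", "c1", "c2", "c4"))
  d <- pool_diagnostics(pool)
  expect_equal(d$dominance, 0.4)
  expect_equal(d$goods_u, 0.9)
  perm <- pool[sample(nrow(pool)), ]
  expect_equal(pool_diagnostics(perm), d)

  empty <- pool[0, ]
  d0 <- pool_diagnostics(empty)
  expect_equal(d0$n_occurrences, 0)
  expect_true(is.na(d0$goods_u) && is.na(d0$dominance))
})

test_that("reference threshold flags but keeps estimates", {
  est <- data.frame(n_refs = c(21, 0, 20, 19))
  out <- reference_threshold_filter(est, min_refs = 20)
  expect_equal(out$reportable, c(TRUE, FALSE, TRUE, FALSE))
  set.seed(1)
  est2 <- data.frame(n_refs = sample(0:60, 50, replace = TRUE))
  out2 <- reference_threshold_filter(est2, min_refs = 20)
  expect_equal(out2$reportable, est2$n_refs >= 20)
  expect_equal(nrow(out2), 50)
})

test_that("the packaged bin scheme is a valid ~9-myr Tr1-Pg2 series", {
  bins <- default_time_bins()
  expect_s3_class(bins, "time_bins")
  expect_equal(bins$name[1], "Tr1")
  expect_equal(bins$name[nrow(bins)], "Pg2")
  expect_true(all(bins$duration_myr > 4 & bins$duration_myr < 13))
  expect_true(all(abs(bins$start_ma[-1] - bins$end_ma[-nrow(bins)]) < 1e-9))
})
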