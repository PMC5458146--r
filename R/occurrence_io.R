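#' Column mapping for PaleoDB-style occurrence downloads
#'
#' Maps the package's canonical occurrence fields onto the column headers of
#' a CSV file. The default mirrors Paleobiology Database download headers.
#' Flag columns (`flag_marine`, `flag_flying`, `flag_ichno`, `flag_oo`,
#' `flag_soft_tissue`, `flag_wastebasket`) are optional in the file; missing
#' flags are taken as FALSE.
#'
#' @param ... overrides of individual mappings, e.g. `palaeolat = "lat"`.
#' @return named list mapping canonical field -> file column.
#' @export
paleodb_dialect <- function(...) {
  d <- list(
    occurrence_id   = "occurrence_no",
    collection_id   = "collection_no",
    taxon_name      = "accepted_name",
    taxon_rank      = "accepted_rank",
    reference_id    = "reference_no",
    palaeolat       = "paleolat",
    palaeolon       = "paleolng",
    interval_max_ma = "max_ma",
    interval_min_ma = "min_ma"
  )
  utils::modifyList(d, list(...))
}

FLAG_FIELDS <- c("marine", "flying", "ichno", "oo", "soft_tissue", "wastebasket")
TAXON_RANKS <- c("species", "genus", "indeterminate")

canonical_columns <- function() {
  c("occurrence_id", "collection_id", "taxon_name", "taxon_rank",
    "reference_id", "palaeolat", "palaeolon",
    "interval_max_ma", "interval_min_ma", paste0("flag_", FLAG_FIELDS))
}

#' Read and validate a PaleoDB-style occurrence table
#'
#' Reads a CSV of fossil occurrences, renames columns through a dialect
#' mapping, and validates every row (coordinate bounds, interval ordering,
#' non-empty identifiers). Malformed rows are collected -- with their row
#' numbers -- rather than silently dropped; valid rows are returned in file
#' order.
#'
#' @param path CSV file path.
#' @param dialect column mapping from [paleodb_dialect()].
#' @return data.frame of validated occurrence records in canonical columns,
#'   with attribute `"errors"`: a data.frame (`row`, `field`, `message`) of
#'   rejected rows (zero rows when the file is clean).
#' @export
read_occurrence_table <- function(path, dialect = paleodb_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(unlist(dialect), names(raw))
  if (length(missing_cols))
    stop("mandatory column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- data.frame(row.names = NULL, stringsAsFactors = FALSE)
  n <- nrow(raw)
  df <- data.frame(
    occurrence_id   = raw[[dialect$occurrence_id]],
    collection_id   = raw[[dialect$collection_id]],
    taxon_name      = raw[[dialect$taxon_name]],
    taxon_rank      = tolower(trimws(raw[[dialect$taxon_rank]])),
    reference_id    = raw[[dialect$reference_id]],
    palaeolat       = suppressWarnings(as.numeric(raw[[dialect$palaeolat]])),
    palaeolon       = suppressWarnings(as.numeric(raw[[dialect$palaeolon]])),
    interval_max_ma = suppressWarnings(as.numeric(raw[[dialect$interval_max_ma]])),
    interval_min_ma = suppressWarnings(as.numeric(raw[[dialect$interval_min_ma]])),
    stringsAsFactors = FALSE
  )
  # ranks outside the recognised set are treated as indeterminate
  df$taxon_rank[!(df$taxon_rank %in% TAXON_RANKS)] <- "indeterminate"
  for (f in FLAG_FIELDS) {
    col <- paste0("flag_", f)
    src <- if (!is.null(dialect[[col]])) dialect[[col]] else col
    df[[col]] <- if (src %in% names(raw)) {
      v <- tolower(trimws(raw[[src]]))
      v %in% c("true", "t", "1", "yes")
    } else rep(FALSE, n)
  }
  v <- validate_occurrences(df)
  records <- v$records
  attr(records, "errors") <- v$errors
  records
}

# Row-level validation shared by the reader and the generator round-trip
validate_occurrences <- function(df) {
  n <- nrow(df)
  errs <- list()
  bad <- rep(FALSE, n)
  flag <- function(idx, field, msg) {
    if (any(idx)) {
      errs[[length(errs) + 1]] <<- data.frame(
        row = which(idx), field = field, message = msg,
        stringsAsFactors = FALSE)
      bad <<- bad | idx
    }
  }
  df$palaeolon <- ifelse(is.na(df$palaeolon), NA_real_, normalize_lon(df$palaeolon))
  flag(is.na(df$palaeolat) | df$palaeolat < -90 | df$palaeolat > 90,
       "palaeolat", "palaeolatitude missing or outside [-90, 90]")
  flag(is.na(df$palaeolon) | df$palaeolon <= -180 | df$palaeolon > 180,
       "palaeolon", "palaeolongitude missing or outside (-180, 180]")
  flag(is.na(df$interval_max_ma) | is.na(df$interval_min_ma) |
         df$interval_min_ma < 0 | df$interval_max_ma < df$interval_min_ma,
       "interval", "interval ages missing, negative, or max < min")
  for (idcol in c("occurrence_id", "collection_id", "reference_id")) {
    flag(is.na(df[[idcol]]) | !nzchar(trimws(df[[idcol]])), idcol,
         paste0(idcol, " empty"))
  }
  errors <- if (length(errs)) do.call(rbind, errs) else
    data.frame(row = integer(0), field = character(0), message = character(0),
               stringsAsFactors = FALSE)
  errors <- errors[order(errors$row), , drop = FALSE]
  rownames(errors) <- NULL
  records <- df[!bad, , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, errors = errors)
}

#' Write an occurrence table in a CSV dialect
#'
#' Inverse of [read_occurrence_table()]: canonical columns are renamed through
#' the dialect before writing, so a written table re-reads to identical
#' records.
#'
#' @param records occurrence data.frame in canonical columns.
#' @param path output CSV path.
#' @param dialect column mapping from [paleodb_dialect()].
#' @return `path`, invisibly.
#' @export
write_occurrence_table <- function(records, path, dialect = paleodb_dialect()) {
  out <- records
  canon <- names(dialect)
  nm <- names(out)
  nm[match(canon, nm)] <- unlist(dialect)[canon]
  names(out) <- nm
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Remove excluded taxa and preservation classes
#'
#' Cleans an occurrence table by dropping generically indeterminate records
#' and records carrying excluded flags (marine, flying, ichnotaxa, ootaxa,
#' soft-tissue preservation) or matching a user-supplied wastebasket-taxon
#' name list. The package deliberately does not hard-code taxonomy: which
#' names count as wastebasket taxa is the caller's decision.
#'
#' @param records occurrence data.frame.
#' @param flags character vector of flag categories to exclude (subset of
#'   `marine`, `flying`, `ichno`, `oo`, `soft_tissue`, `wastebasket`).
#' @param wastebasket_taxa character vector of taxon names to exclude.
#' @param drop_indeterminate drop records with `taxon_rank == "indeterminate"`
#'   (default TRUE).
#' @return filtered data.frame with attribute `"exclusion_tally"`: named
#'   integer counts of records matching each filter category (a record
#'   matching several categories is tallied in each, but removed once).
#' @export
apply_taxon_filters <- function(records,
                                flags = FLAG_FIELDS,
                                wastebasket_taxa = character(0),
                                drop_indeterminate = TRUE) {
  stopifnot(all(flags %in% FLAG_FIELDS))
  drop <- rep(FALSE, nrow(records))
  tally <- integer(0)
  for (f in flags) {
    hit <- records[[paste0("flag_", f)]]
    tally[f] <- sum(hit)
    drop <- drop | hit
  }
  hit_wb <- records$taxon_name %in% wastebasket_taxa
  tally["wastebasket_name"] <- sum(hit_wb)
  drop <- drop | hit_wb
  if (drop_indeterminate) {
    hit_ind <- records$taxon_rank == "indeterminate"
    tally["indeterminate"] <- sum(hit_ind)
    drop <- drop | hit_ind
  }
  tally["total_removed"] <- sum(drop)
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusion_tally") <- tally
  out
}

#' Build a time-bin scheme
#'
#' @param name bin labels, ordered oldest first.
#' @param start_ma,end_ma bin boundaries in Ma; `start_ma > end_ma` per bin,
#'   bins non-overlapping.
#' @return data.frame of class `time_bins` with `name`, `start_ma`, `end_ma`,
#'   `duration_myr`, `midpoint_ma`.
#' @export
time_bins <- function(name, start_ma, end_ma) {
  stopifnot(length(name) == length(start_ma), length(name) == length(end_ma))
  if (any(start_ma <= end_ma))
    stop("each bin needs start_ma > end_ma", call. = FALSE)
  bins <- data.frame(name = as.character(name), start_ma = start_ma,
                     end_ma = end_ma, stringsAsFactors = FALSE)
  bins <- bins[order(-bins$start_ma), , drop = FALSE]
  if (any(duplicated(bins$name))) stop("duplicate bin names", call. = FALSE)
  # overlap: a younger bin starting before the previous one has ended
  if (nrow(bins) > 1 &&
      any(bins$start_ma[-1] > bins$end_ma[-nrow(bins)] + 1e-9))
    stop("time bins overlap", call. = FALSE)
  bins$duration_myr <- bins$start_ma - bins$end_ma
  bins$midpoint_ma <- (bins$start_ma + bins$end_ma) / 2
  rownames(bins) <- NULL
  class(bins) <- c("time_bins", "data.frame")
  bins
}

#' Read a time-bin scheme from CSV
#' @param path CSV with columns `name`, `start_ma`, `end_ma`.
#' @return a `time_bins` data.frame.
#' @export
read_time_bins <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  time_bins(df$name, df$start_ma, df$end_ma)
}

#' Packaged Triassic--early-Palaeogene bin scheme
#'
#' Approximately equal ~9-myr divisions of the Triassic through Ypresian
#' (Tr1--Pg2), constructed from ICS stage boundary ages. The scheme is
#' approximate: it is intended as a sensible default, not an authority on
#' boundary ages.
#'
#' @return a `time_bins` data.frame.
#' @export
default_time_bins <- function() {
  read_time_bins(system.file("extdata", "time_bins_tr1_pg2.csv",
                             package = "fossilspread", mustWork = TRUE))
}

#' Assign occurrences to time bins by full containment
#'
#' A record is assigned to a bin only when its age interval lies entirely
#' within the bin (closed containment: ages exactly on a bin boundary count
#' as inside). Records spanning a bin boundary get `NA` and are excluded
#' from per-bin pools. When an interval touches the shared boundary of two
#' bins exactly (zero-width interval on the boundary), the older bin wins.
#'
#' @param records occurrence data.frame.
#' @param bins a `time_bins` scheme.
#' @return `records` with an added character column `bin` (`NA` = unassigned).
#' @export
assign_time_bins <- function(records, bins) {
  if (!inherits(bins, "time_bins")) bins <- time_bins(bins$name, bins$start_ma, bins$end_ma)
  bin <- rep(NA_character_, nrow(records))
  for (i in seq_len(nrow(bins))) {  # oldest first: first match wins
    hit <- is.na(bin) &
      records$interval_max_ma <= bins$start_ma[i] + 1e-9 &
      records$interval_min_ma >= bins$end_ma[i] - 1e-9
    bin[hit] <- bins$name[i]
  }
  records$bin <- bin
  records
}

#' Collapse duplicate taxon-collection occurrences
#'
#' PaleoDB occurrence semantics treat repeated listings of one taxon within
#' one collection as a single occurrence; counting routines here assume that
#' collapse has been applied.
#'
#' @param records occurrence data.frame.
#' @return records with at most one row per (taxon_name, collection_id) pair
#'   (first row kept).
#' @export
collapse_duplicates <- function(records) {
  keep <- !duplicated(paste(records$taxon_name, records$collection_id, sep = "\r"))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sampling diagnostics of an occurrence pool
#'
#' Counts and ratio diagnostics used to judge sampling effort: occurrence,
#' collection and reference counts, raw richness, Good's u (coverage) and
#' dominance (relative frequency of the most common taxon).
#'
#' @param pool occurrence data.frame (one region x bin, or one spatial
#'   sample).
#' @param collapse collapse duplicate taxon-collection rows first
#'   (default TRUE).
#' @param singleton_rule passed to [goods_u()].
#' @return one-row data.frame: `n_occurrences`, `n_collections`,
#'   `n_references`, `raw_richness`, `goods_u`, `dominance` (ratios NA for an
#'   empty pool).
#' @export
pool_diagnostics <- function(pool, collapse = TRUE,
                             singleton_rule = c("by_collection", "by_occurrence")) {
  singleton_rule <- match.arg(singleton_rule)
  if (collapse) pool <- collapse_duplicates(pool)
  n <- nrow(pool)
  if (n == 0) {
    return(data.frame(n_occurrences = 0L, n_collections = 0L, n_references = 0L,
                      raw_richness = 0L, goods_u = NA_real_, dominance = NA_real_))
  }
  counts <- table(pool$taxon_name)
  data.frame(
    n_occurrences = n,
    n_collections = length(unique(pool$collection_id)),
    n_references = length(unique(pool$reference_id)),
    raw_richness = length(counts),
    goods_u = goods_u(pool, singleton_rule = singleton_rule, collapse = FALSE),
    dominance = as.numeric(max(counts)) / n
  )
}

#' Flag richness estimates below the reference threshold
#'
#' Estimates from pools tied to few distinct references reflect too little
#' worker effort to be reportable; they are flagged, not removed.
#'
#' @param estimates data.frame with a column `n_refs` (or `n_references`).
#' @param min_refs minimum distinct references for a reportable estimate
#'   (default 20; an estimate is reportable when `n_refs >= min_refs`).
#' @return `estimates` with an added logical column `reportable`.
#' @export
reference_threshold_filter <- function(estimates, min_refs = 20) {
  col <- intersect(c("n_refs", "n_references"), names(estimates))[1]
  if (is.na(col)) stop("estimates need an n_refs / n_references column", call. = FALSE)
  estimates$reportable <- estimates[[col]] >= min_refs
  estimates
}
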