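# connected components of an edge list over known vertex ids
edge_components <- function(cell_ids, edges) {
  comp <- stats::setNames(seq_along(cell_ids), cell_ids)
  if (nrow(edges)) {
    # union-find with path halving
    find <- function(i) {
      while (comp[i] != i) {
        comp[i] <<- comp[comp[i]]
        i <- comp[i]
      }
      i
    }
    ia <- match(edges$from, cell_ids)
    ib <- match(edges$to, cell_ids)
    for (k in seq_len(nrow(edges))) {
      ra <- find(ia[k]); rb <- find(ib[k])
      if (ra != rb) comp[rb] <- ra
    }
    for (i in seq_along(comp)) comp[i] <- find(i)
  }
  split(cell_ids, comp[cell_ids])
}

make_subtree <- function(id, cells, edges, bin = NA_character_) {
  out <- list(subtree_id = id, cells = cells, edges = edges,
              total_km = sum(edges$km), bin = bin)
  class(out) <- "regional_subtree"
  out
}

#' @export
print.regional_subtree <- function(x, ...) {
  cat("Regional subtree", x$subtree_id, ":", nrow(x$cells), "cells, summed MST",
      format(round(x$total_km, 1), big.mark = ","), "km\n")
  invisible(x)
}

#' Split a global MST into continental-scale subtrees
#'
#' Long branches (intercontinental connections) are removed by iteratively
#' deleting the longest edge of any component whose summed length is at or
#' above the ceiling, until every component is below it. Components whose
#' summed length then falls below `min_km` are dropped (they are too small to
#' yield an equal-spread sample). Ties on edge length are broken by the
#' lexicographically smaller (from, to) pair, so splitting is deterministic.
#'
#' @param mst a `spatial_mst` from [build_mst()].
#' @param ceiling_km components at or above this summed length keep being
#'   split (default 13000 km, chosen to isolate continent-sized regions).
#' @param min_km drop subtrees below this summed length; default
#'   `target_km * (1 - tol)`, the lower edge of the sampling band.
#' @param target_km,tol used only for the `min_km` default (3200 km, 10%).
#' @param bin optional bin label carried on the subtrees.
#' @return list of `regional_subtree` objects (possibly empty), ordered by
#'   decreasing summed length, labelled `"R1"`, `"R2"`, ...
#' @export
split_global_mst <- function(mst, ceiling_km = 13000, min_km = NULL,
                             target_km = 3200, tol = 0.10,
                             bin = NA_character_) {
  stopifnot(inherits(mst, "spatial_mst"))
  if (is.null(min_km)) min_km <- target_km * (1 - tol)
  cells <- mst$cells
  edges <- mst$edges
  repeat {
    comps <- edge_components(cells$cell_id, edges)
    too_big <- FALSE
    for (members in comps) {
      in_comp <- edges$from %in% members  # tree edges: both ends in one comp
      if (!any(in_comp)) next
      len <- sum(edges$km[in_comp])
      if (len >= ceiling_km) {
        too_big <- TRUE
        cand <- which(in_comp)
        mx <- max(edges$km[cand])
        at_max <- cand[edges$km[cand] >= mx - 1e-9]
        pick <- at_max[order(edges$from[at_max], edges$to[at_max])][1]
        edges <- edges[-pick, , drop = FALSE]
      }
    }
    if (!too_big) break
  }
  finalize_subtrees(cells, edges, min_km, bin)
}

finalize_subtrees <- function(cells, edges, min_km, bin = NA_character_) {
  comps <- edge_components(cells$cell_id, edges)
  comps <- comps[order(-vapply(comps, function(m)
    sum(edges$km[edges$from %in% m]), numeric(1)))]
  out <- list()
  for (members in comps) {
    e <- edges[edges$from %in% members, , drop = FALSE]
    len <- sum(e$km)
    if (len < min_km) next
    out[[length(out) + 1]] <- make_subtree(
      paste0("R", length(out) + 1),
      cells[cells$cell_id %in% members, , drop = FALSE],
      e, bin = bin)
  }
  out
}

#' Remove user-supplied biogeographic barrier edges
#'
#' Branches crossing biogeographic barriers (for example, land bridges the
#' analyst judges uncrossable) are removed from the subtrees and the
#' resulting components re-evaluated against `min_km`. Barrier pairs that
#' match no current edge raise a warning and are ignored.
#'
#' @param subtrees list of `regional_subtree` objects.
#' @param barriers data.frame with columns `from`, `to` (cell ids, either
#'   orientation).
#' @param min_km drop resulting components below this summed length.
#' @return re-split list of `regional_subtree` objects.
#' @export
remove_barrier_edges <- function(subtrees, barriers, min_km = 3200 * 0.9) {
  if (is.null(barriers) || nrow(barriers) == 0) return(subtrees)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  bkey <- key(as.character(barriers$from), as.character(barriers$to))
  matched <- rep(FALSE, length(bkey))
  out <- list()
  for (st in subtrees) {
    ekey <- key(st$edges$from, st$edges$to)
    hit <- ekey %in% bkey
    matched <- matched | bkey %in% ekey
    if (!any(hit)) {
      out[[length(out) + 1]] <- st
      next
    }
    pieces <- finalize_subtrees(st$cells, st$edges[!hit, , drop = FALSE], min_km,
                                bin = st$bin)
    out <- c(out, pieces)
  }
  if (any(!matched))
    warning("barrier pair(s) matching no edge ignored: ",
            paste(bkey[!matched], collapse = ", "), call. = FALSE)
  if (length(out))
    for (i in seq_along(out)) out[[i]]$subtree_id <- paste0("R", i)
  out
}

#' Grow one equal-spread spatial sample
#'
#' Starting from a uniformly random cell of the regional subtree, the sample
#' repeatedly adds the frontier cell (a cell adjacent in the subtree's MST to
#' the current sample) joined by the shortest connecting edge, so the induced
#' subtree length grows monotonically. Growth stops once the induced length
#' reaches the target; the state with or without the final cell -- whichever
#' lands closer to the target -- is accepted, provided it falls within the
#' tolerance band `target_km * (1 +/- tol)`. A subtree exhausted before the
#' target is accepted only if its full length is inside the band.
#'
#' @param subtree a `regional_subtree`.
#' @param target_km target summed MST length (default 3200 km).
#' @param tol acceptance tolerance as a fraction of the target (default 0.10).
#' @param rng_seed optional seed for the starting-cell draw.
#' @param start_cell force the seed cell (mainly for testing).
#' @return list of class `spatial_sample`. On acceptance: `accepted = TRUE`,
#'   `seed_cell`, `cells` (cell ids in growth order), `induced_mst_km`,
#'   `growth_km` (cumulative length after each addition), `target_km`, `tol`.
#'   On rejection: `accepted = FALSE` with a `reason`.
#' @export
grow_spatial_sample <- function(subtree, target_km = 3200, tol = 0.10,
                                rng_seed = NULL, start_cell = NULL) {
  stopifnot(inherits(subtree, "regional_subtree"))
  lo <- target_km * (1 - tol)
  hi <- target_km * (1 + tol)
  reject <- function(reason, seed = NA_character_) {
    structure(list(accepted = FALSE, reason = reason, seed_cell = seed,
                   target_km = target_km, tol = tol),
              class = "spatial_sample")
  }
  if (subtree$total_km < lo - 1e-9)
    return(reject("subtree summed MST length below target band"))
  ids <- subtree$cells$cell_id
  seed_cell <- with_local_seed(rng_seed, {
    if (is.null(start_cell)) ids[sample.int(length(ids), 1)] else start_cell
  })
  stopifnot(seed_cell %in% ids)
  edges <- subtree$edges
  n_e <- nrow(edges)
  in_sample <- stats::setNames(rep(FALSE, length(ids)), ids)
  in_sample[seed_cell] <- TRUE
  used <- rep(FALSE, n_e)
  order_added <- seed_cell
  growth <- numeric(0)
  cum <- 0
  while (cum < target_km - 1e-9) {
    a_in <- in_sample[edges$from]
    b_in <- in_sample[edges$to]
    frontier <- which(!used & xor(a_in, b_in))
    if (!length(frontier)) break
    mn <- min(edges$km[frontier])
    at_min <- frontier[edges$km[frontier] <= mn + 1e-12]
    pick <- at_min[order(edges$from[at_min], edges$to[at_min])][1]
    new_cell <- if (in_sample[edges$from[pick]]) edges$to[pick] else edges$from[pick]
    in_sample[new_cell] <- TRUE
    used[pick] <- TRUE
    cum <- cum + edges$km[pick]
    order_added <- c(order_added, new_cell)
    growth <- c(growth, cum)
  }
  if (cum >= target_km - 1e-9 && length(growth) >= 1) {
    without <- if (length(growth) >= 2) growth[length(growth) - 1] else 0
    if (abs(cum - target_km) <= abs(without - target_km)) {
      final_len <- cum
    } else {
      final_len <- without
      order_added <- order_added[-length(order_added)]
      growth <- growth[-length(growth)]
    }
  } else {
    final_len <- cum  # subtree exhausted before the target
  }
  if (final_len < lo - 1e-9 || final_len > hi + 1e-9)
    return(reject(sprintf("accepted length %.1f km outside band [%.1f, %.1f]",
                          final_len, lo, hi), seed_cell))
  structure(list(accepted = TRUE, seed_cell = seed_cell, cells = order_added,
                 induced_mst_km = final_len, growth_km = growth,
                 target_km = target_km, tol = tol),
            class = "spatial_sample")
}

#' @export
print.spatial_sample <- function(x, ...) {
  if (isTRUE(x$accepted)) {
    cat(sprintf("Equal-spread sample: %d cells, induced MST %.1f km (target %.0f km +/- %.0f%%)\n",
                length(x$cells), x$induced_mst_km, x$target_km, 100 * x$tol))
  } else {
    cat("Rejected spatial sample:", x$reason, "\n")
  }
  invisible(x)
}

#' Draw replicate equal-spread samples from a regional subtree
#'
#' Draws `n_reps` independent equal-spread samples, each from its own random
#' starting cell. Per-replicate random streams are derived from the master
#' seed, so the full replicate set is reproducible bit-for-bit. A rejected
#' draw is retried (fresh starting cell) up to `max_retries` times; a subtree
#' yielding no acceptance at all is marked unsampleable.
#'
#' @param subtree a `regional_subtree`.
#' @param n_reps number of replicates (default 20).
#' @param target_km,tol as in [grow_spatial_sample()].
#' @param master_seed integer seed for the whole replicate set.
#' @param max_retries retry cap per replicate (default 100).
#' @return list of accepted `spatial_sample`s (with `replicate_id` set), with
#'   attributes `manifest` (data.frame: replicate_id, seed_cell, n_cells,
#'   induced_mst_km, accepted, attempts) and `unsampleable` (logical).
#' @export
replicate_spatial_samples <- function(subtree, n_reps = 20, target_km = 3200,
                                      tol = 0.10, master_seed = NULL,
                                      max_retries = 100) {
  rep_seeds <- with_local_seed(master_seed,
                               sample.int(.Machine$integer.max, n_reps))
  samples <- list()
  rows <- list()
  for (r in seq_len(n_reps)) {
    res <- with_local_seed(rep_seeds[r], {
      attempt <- 0L
      s <- NULL
      repeat {
        attempt <- attempt + 1L
        s <- grow_spatial_sample(subtree, target_km = target_km, tol = tol)
        if (isTRUE(s$accepted) ||
            identical(s$reason, "subtree summed MST length below target band") ||
            attempt >= max_retries) break
      }
      list(sample = s, attempts = attempt)
    })
    s <- res$sample
    rows[[r]] <- data.frame(
      replicate_id = r,
      seed_cell = if (is.null(s$seed_cell)) NA_character_ else s$seed_cell,
      n_cells = if (isTRUE(s$accepted)) length(s$cells) else NA_integer_,
      induced_mst_km = if (isTRUE(s$accepted)) s$induced_mst_km else NA_real_,
      accepted = isTRUE(s$accepted),
      attempts = res$attempts,
      stringsAsFactors = FALSE)
    if (isTRUE(s$accepted)) {
      s$replicate_id <- r
      samples[[length(samples) + 1]] <- s
    }
  }
  manifest <- do.call(rbind, rows)
  attr(samples, "manifest") <- manifest
  attr(samples, "unsampleable") <- length(samples) == 0
  samples
}

#' Occurrences of the collections inside a spatial sample
#'
#' @param sample an accepted `spatial_sample`.
#' @param cells the `grid_cells` the parent MST was built from (holding the
#'   collection membership of every cell).
#' @param occurrences the occurrence table.
#' @return the subset of `occurrences` whose collections fall in the sample's
#'   grid cells.
#' @export
sample_occurrences <- function(sample, cells, occurrences) {
  stopifnot(isTRUE(sample$accepted))
  idx <- match(sample$cells, cells$cell_id)
  colls <- unlist(cells$member_collections[idx], use.names = FALSE)
  out <- occurrences[occurrences$collection_id %in% colls, , drop = FALSE]
  rownames(out) <- NULL
  out
}
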