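#' Good's u coverage estimator
#'
#' u = 1 - (number of singleton taxa) / (number of occurrences), clamped to
#' [0, 1]. Under the default occurrence-based subsampling convention a
#' singleton is a taxon found in exactly one collection; the by-occurrence
#' variant (exactly one occurrence) is exposed for sensitivity analyses.
#' Good's u estimates the coverage of the sampling pool and is the maximum
#' quorum achievable by SQS for that pool.
#'
#' @param pool occurrence data.frame with `taxon_name`, `collection_id`.
#' @param singleton_rule `"by_collection"` (default) or `"by_occurrence"`.
#' @param collapse collapse duplicate taxon-collection rows first.
#' @return coverage in [0, 1], or NA for an empty pool.
#' @export
goods_u <- function(pool, singleton_rule = c("by_collection", "by_occurrence"),
                    collapse = TRUE) {
  singleton_rule <- match.arg(singleton_rule)
  if (collapse) pool <- collapse_duplicates(pool)
  n <- nrow(pool)
  if (n == 0) return(NA_real_)
  n_singletons <- if (singleton_rule == "by_collection") {
    colls <- tapply(pool$collection_id, pool$taxon_name,
                    function(x) length(unique(x)))
    sum(colls == 1)
  } else {
    sum(table(pool$taxon_name) == 1)
  }
  min(max(1 - n_singletons / n, 0), 1)
}

#' SQS configuration
#'
#' @param quorum target coverage in (0, 1); default 0.4.
#' @param n_trials subsampling trials to average over; default 100.
#' @param singleton_rule singleton definition for Good's u.
#' @param exclude_dominant ignore the most common taxon's frequency share in
#'   the coverage tally (off by default).
#' @return list of class `sqs_config`.
#' @export
sqs_config <- function(quorum = 0.4, n_trials = 100,
                       singleton_rule = c("by_collection", "by_occurrence"),
                       exclude_dominant = FALSE) {
  stopifnot(quorum > 0, quorum < 1, n_trials >= 1)
  structure(list(quorum = quorum, n_trials = as.integer(n_trials),
                 singleton_rule = match.arg(singleton_rule),
                 exclude_dominant = isTRUE(exclude_dominant)),
            class = "sqs_config")
}

# run a function with a locally-seeded RNG, restoring global state after
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Shareholder quorum subsampling (coverage-based rarefaction)
#'
#' Occurrence-based SQS: in each trial, whole collections are drawn in a
#' uniformly random order; after each draw the coverage reached so far is the
#' summed occurrence-frequency share (from the full pool) of the distinct
#' taxa drawn, multiplied by Good's u to estimate coverage of the true
#' sampling pool. Drawing stops once coverage reaches the quorum, and the
#' trial's richness is the number of distinct taxa drawn. The estimate is the
#' mean trial richness.
#'
#' @param pool occurrence data.frame.
#' @param cfg an [sqs_config()].
#' @param rng_seed optional integer seed (RNG state is restored afterwards).
#' @param collapse collapse duplicate taxon-collection rows first.
#' @return list of class `sqs_estimate`: `richness` (mean across trials),
#'   `sd`, `n_trials`, `quorum`, `u`. When the quorum exceeds Good's u the
#'   estimate is undefined: `richness` is NA and `reason` says why.
#' @export
sqs_richness <- function(pool, cfg = sqs_config(), rng_seed = NULL,
                         collapse = TRUE) {
  stopifnot(inherits(cfg, "sqs_config"))
  if (collapse) pool <- collapse_duplicates(pool)
  n <- nrow(pool)
  empty <- list(richness = NA_real_, sd = NA_real_, n_trials = cfg$n_trials,
                quorum = cfg$quorum, u = NA_real_, reason = "empty pool")
  class(empty) <- "sqs_estimate"
  if (n == 0) return(empty)
  u <- goods_u(pool, singleton_rule = cfg$singleton_rule, collapse = FALSE)
  if (cfg$quorum > u + 1e-12) {
    out <- empty
    out$u <- u
    out$reason <- sprintf("quorum %.3f exceeds Good's u %.3f", cfg$quorum, u)
    return(out)
  }
  taxa <- factor(pool$taxon_name)
  n_taxa <- nlevels(taxa)
  share <- as.numeric(table(taxa)) / n
  if (cfg$exclude_dominant) share[which.max(share)] <- 0
  coll <- factor(pool$collection_id)
  taxa_by_coll <- split(as.integer(taxa), coll)
  n_coll <- nlevels(coll)
  trial_richness <- with_local_seed(rng_seed, {
    vapply(seq_len(cfg$n_trials), function(trial) {
      ord <- sample.int(n_coll)
      seen <- logical(n_taxa)
      cov <- 0
      rich <- 0L
      for (ci in ord) {
        tx <- taxa_by_coll[[ci]]
        new <- tx[!seen[tx]]
        if (length(new)) {
          seen[new] <- TRUE
          cov <- cov + sum(share[new])
          rich <- rich + length(new)
        }
        if (u * cov >= cfg$quorum - 1e-12) break
      }
      as.numeric(rich)
    }, numeric(1))
  })
  out <- list(richness = mean(trial_richness), sd = stats::sd(trial_richness),
              n_trials = cfg$n_trials, quorum = cfg$quorum, u = u,
              reason = NA_character_)
  class(out) <- "sqs_estimate"
  out
}

#' Zero-truncated-Poisson MLE of the sampling rate
#'
#' Solves lambda / (1 - exp(-lambda)) = mean(counts) by bracketed root
#' finding with Newton polishing (|residual| < 1e-10). When every taxon is a
#' single occurrence (mean = 1) the MLE sits on the lambda = 0 boundary and
#' the estimate is flagged degenerate.
#'
#' @param counts per-taxon occurrence counts, all >= 1.
#' @return list: `lambda_hat`, `degenerate`, `residual`.
#' @export
ztp_lambda_mle <- function(counts) {
  stopifnot(length(counts) >= 1, all(counts >= 1))
  m <- mean(counts)
  if (m <= 1 + 1e-12)
    return(list(lambda_hat = 0, degenerate = TRUE, residual = NA_real_))
  g <- function(l) l / (1 - exp(-l))
  # g is increasing with g(0+) = 1 and g(l) > l, so the root lies in (0, m]
  lo <- 1e-10
  root <- stats::uniroot(function(l) g(l) - m, c(lo, m),
                         tol = .Machine$double.eps^0.75)$root
  for (i in 1:4) {  # Newton polish: g'(l) = (1 - e^-l - l e^-l) / (1 - e^-l)^2
    el <- exp(-root)
    deriv <- (1 - el - root * el) / (1 - el)^2
    root <- root - (g(root) - m) / deriv
  }
  list(lambda_hat = root, degenerate = FALSE, residual = abs(g(root) - m))
}

ztp_loglik <- function(lambda, counts) {
  n <- length(counts)
  sum(counts) * log(lambda) - n * lambda - n * log1p(-exp(-lambda))
}

#' TRiPS richness estimate from a Poisson sampling model
#'
#' Models per-species fossil sampling within a bin as a Poisson process:
#' observed per-taxon occurrence counts are zero-truncated Poisson(lambda),
#' the detection probability is p = 1 - exp(-lambda), and estimated richness
#' is n_observed / p. The 95% interval combines a profile-likelihood interval
#' on lambda (chi-square(1) cutoff) with binomial uncertainty in n_observed,
#' by inverting the binomial at the profile bounds of p: the lower richness
#' bound is the smallest N for which observing at least n_observed species at
#' detection probability p_high is not improbable (tail >= 0.025), the upper
#' bound the largest N for which observing at most n_observed species at
#' p_low is not improbable.
#'
#' @param pool occurrence data.frame, or a numeric vector of per-taxon
#'   counts.
#' @param collapse collapse duplicate taxon-collection rows first (table
#'   input only).
#' @return list of class `trips_estimate`: `lambda_hat`, `lambda_lo`,
#'   `lambda_hi`, `p_hat`, `n_observed`, `richness_hat`, `ci_low`, `ci_high`,
#'   `degenerate`. A boundary MLE (all counts 1) yields NA richness with
#'   `degenerate = TRUE`.
#' @export
trips_richness <- function(pool, collapse = TRUE) {
  counts <- if (is.numeric(pool)) pool else {
    if (collapse) pool <- collapse_duplicates(pool)
    as.numeric(table(pool$taxon_name))
  }
  n_obs <- length(counts)
  out <- list(lambda_hat = NA_real_, lambda_lo = NA_real_, lambda_hi = NA_real_,
              p_hat = NA_real_, n_observed = n_obs, richness_hat = NA_real_,
              ci_low = NA_real_, ci_high = NA_real_, degenerate = TRUE)
  class(out) <- "trips_estimate"
  if (n_obs == 0) return(out)
  mle <- ztp_lambda_mle(counts)
  if (mle$degenerate) {
    out$lambda_hat <- 0
    return(out)
  }
  lam <- mle$lambda_hat
  ll_max <- ztp_loglik(lam, counts)
  cut <- ll_max - stats::qchisq(0.95, df = 1) / 2
  f <- function(l) ztp_loglik(l, counts) - cut
  lam_lo <- stats::uniroot(f, c(1e-12, lam), tol = 1e-10)$root
  hi <- lam * 2 + 1
  while (f(hi) > 0) hi <- hi * 2
  lam_hi <- stats::uniroot(f, c(lam, hi), tol = 1e-10)$root
  p_hat <- 1 - exp(-lam)
  p_lo <- 1 - exp(-lam_lo)
  p_hi <- 1 - exp(-lam_hi)
  # binomial inversion on N at the profile bounds of p:
  # lower bound: smallest N with P(Binomial(N, p_hi) >= n_obs) >= 0.025;
  # upper bound: largest N with P(Binomial(N, p_lo) <= n_obs) >= 0.025
  n_max <- ceiling(n_obs / p_lo * 4 + 100)
  nn <- n_obs:n_max
  ok_lo <- 1 - stats::pbinom(n_obs - 1, nn, p_hi) >= 0.025
  ci_low <- if (!any(ok_lo)) n_obs else nn[min(which(ok_lo))]
  ok <- stats::pbinom(n_obs, nn, p_lo) >= 0.025
  ci_high <- if (all(ok)) Inf else nn[max(which(ok))]
  out$lambda_hat <- lam
  out$lambda_lo <- lam_lo
  out$lambda_hi <- lam_hi
  out$p_hat <- p_hat
  out$richness_hat <- n_obs / p_hat
  out$ci_low <- as.numeric(min(ci_low, out$richness_hat))
  out$ci_high <- as.numeric(ci_high)
  out$degenerate <- FALSE
  out
}

#' @export
print.trips_estimate <- function(x, ...) {
  if (x$degenerate) {
    cat("TRiPS estimate: degenerate (boundary sampling-rate MLE),",
        x$n_observed, "taxa observed\n")
  } else {
    cat(sprintf(
      "TRiPS estimate: %.1f species (95%% CI %.1f-%.1f); lambda = %.3f, p = %.3f, %d observed\n",
      x$richness_hat, x$ci_low, x$ci_high, x$lambda_hat, x$p_hat, x$n_observed))
  }
  invisible(x)
}

#' Richness estimates for one occurrence pool
#'
#' Raw richness plus SQS and TRiPS estimates with the pool's sampling
#' diagnostics, as one tidy row.
#'
#' @param pool occurrence data.frame.
#' @param cfg an [sqs_config()].
#' @param trips compute the TRiPS estimate (default TRUE).
#' @param rng_seed seed for the SQS trials.
#' @return one-row data.frame: `raw`, `sqs_mean`, `sqs_sd`, `trips_hat`,
#'   `trips_lo`, `trips_hi`, `u`, `dominance`, `n_occ`, `n_coll`, `n_refs`.
#' @export
estimate_richness <- function(pool, cfg = sqs_config(), trips = TRUE,
                              rng_seed = NULL) {
  pool <- collapse_duplicates(pool)
  diag <- pool_diagnostics(pool, collapse = FALSE,
                           singleton_rule = cfg$singleton_rule)
  sqs <- sqs_richness(pool, cfg, rng_seed = rng_seed, collapse = FALSE)
  tr <- if (trips && nrow(pool) > 0) trips_richness(pool, collapse = FALSE) else NULL
  data.frame(
    raw = diag$raw_richness,
    sqs_mean = sqs$richness,
    sqs_sd = sqs$sd,
    trips_hat = if (!is.null(tr) && !tr$degenerate) tr$richness_hat else NA_real_,
    trips_lo = if (!is.null(tr) && !tr$degenerate) tr$ci_low else NA_real_,
    trips_hi = if (!is.null(tr) && !tr$degenerate) tr$ci_high else NA_real_,
    u = diag$goods_u,
    dominance = diag$dominance,
    n_occ = diag$n_occurrences,
    n_coll = diag$n_collections,
    n_refs = diag$n_references
  )
}

#' Estimate richness over many pools, with replicate aggregation
#'
#' Applies [estimate_richness()] to each pool and binds the results to the
#' supplied metadata. In standardized mode the pools are replicate
#' equal-spread samples and the per-replicate estimates are aggregated to a
#' mean (with SD) per region x bin; unstandardized pools pass through as
#' single rows.
#'
#' @param pools list of occurrence data.frames.
#' @param meta data.frame with one row per pool; must contain `region` and
#'   `bin`, and `replicate` in standardized mode.
#' @param cfg an [sqs_config()].
#' @param trips compute TRiPS estimates.
#' @param aggregate aggregate replicates to one row per region x bin.
#' @param rng_seed base seed; pool i uses `rng_seed + i`.
#' @return tidy data.frame of richness estimates.
#' @export
estimate_all <- function(pools, meta, cfg = sqs_config(), trips = TRUE,
                         aggregate = FALSE, rng_seed = NULL) {
  stopifnot(length(pools) == nrow(meta))
  rows <- lapply(seq_along(pools), function(i) {
    seed_i <- if (is.null(rng_seed)) NULL else rng_seed + i
    estimate_richness(pools[[i]], cfg, trips = trips, rng_seed = seed_i)
  })
  out <- cbind(meta, do.call(rbind, rows))
  rownames(out) <- NULL
  if (!aggregate) return(out)
  aggregate_replicates(out)
}

#' Aggregate replicate richness estimates per region x bin
#'
#' @param estimates output of [estimate_all()] with replicate rows.
#' @return one row per region x bin: means of the estimator columns across
#'   replicates with defined values, SDs for raw and SQS, and the replicate
#'   count used.
#' @export
aggregate_replicates <- function(estimates) {
  key <- interaction(estimates$region, estimates$bin, drop = TRUE)
  agg <- lapply(split(estimates, key), function(g) {
    mu <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    sdev <- function(v) if (sum(!is.na(v)) < 2) NA_real_ else stats::sd(v, na.rm = TRUE)
    data.frame(
      region = g$region[1], bin = g$bin[1],
      n_replicates = nrow(g),
      raw = mu(g$raw), raw_sd = sdev(g$raw),
      sqs_mean = mu(g$sqs_mean), sqs_sd = sdev(g$sqs_mean),
      trips_hat = mu(g$trips_hat), trips_sd = sdev(g$trips_hat),
      u = mu(g$u), dominance = mu(g$dominance),
      n_occ = mu(g$n_occ), n_coll = mu(g$n_coll), n_refs = mu(g$n_refs)
    )
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
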