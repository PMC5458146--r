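#' Fit a log-link trend of richness against time
#'
#' Log-linear regression of richness on time-bin midpoint (Ma). Because
#' geological time counts down towards the present, a negative slope means
#' richness increasing towards the present; the slope magnitude is an
#' estimate of the net diversification rate per myr. Raw (count) richness is
#' fit with a negative-binomial error distribution and log link; SQS and
#' TRiPS estimates, which are continuous, with a Gaussian error distribution
#' and log link.
#'
#' @param points data.frame with columns `time_ma` (bin midpoint, Ma) and
#'   `richness` (> 0; non-positive points are excluded with a warning).
#' @param family `"gaussian_log"` or `"negative_binomial_log"`.
#' @param series_label optional label carried on the fit.
#' @return list of class `trend_fit`: `slope`, `se_slope`, `p_slope` (two-
#'   sided Wald), `df` (n - 2), `n_points`, `span_myr`, `ln_increase`
#'   (|slope| x span), `percent_increase` (100 (e^ln - 1)), `family`,
#'   `model` (the underlying glm fit).
#' @export
fit_trend <- function(points, family = c("gaussian_log", "negative_binomial_log"),
                      series_label = NA_character_) {
  family <- match.arg(family)
  stopifnot(all(c("time_ma", "richness") %in% names(points)))
  bad <- !is.finite(points$richness) | points$richness <= 0 |
    !is.finite(points$time_ma)
  if (any(bad)) {
    warning(sum(bad), " point(s) with non-positive or missing richness excluded",
            call. = FALSE)
    points <- points[!bad, , drop = FALSE]
  }
  n <- nrow(points)
  if (n < 3) stop("need at least 3 points to fit a trend", call. = FALSE)
  if (family == "negative_binomial_log") {
    y <- round(points$richness)
    fit <- suppressWarnings(
      MASS::glm.nb(y ~ time_ma, data = data.frame(y = y, time_ma = points$time_ma)))
  } else {
    y <- points$richness
    fit <- stats::glm(y ~ time_ma,
                      data = data.frame(y = y, time_ma = points$time_ma),
                      family = stats::gaussian(link = "log"),
                      start = c(log(mean(y)), 0))
  }
  cf <- summary(fit)$coefficients
  slope <- cf["time_ma", 1]
  se <- cf["time_ma", 2]
  p <- cf["time_ma", 4]
  span <- max(points$time_ma) - min(points$time_ma)
  ln_inc <- abs(slope) * span
  out <- list(series_label = series_label, family = family,
              slope = slope, se_slope = se, p_slope = p,
              df = n - 2L, n_points = n, span_myr = span,
              ln_increase = ln_inc,
              percent_increase = percent_increase(ln_inc),
              model = fit)
  class(out) <- "trend_fit"
  out
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "Trend fit%s (%s): slope %.4f +/- %.4f per myr, P = %.4f, df = %d\n  ln increase %.4f over %.0f myr => %+.0f%% change\n",
    if (is.na(x$series_label)) "" else paste0(" [", x$series_label, "]"),
    x$family, x$slope, x$se_slope, x$p_slope, x$df,
    x$ln_increase, x$span_myr, x$percent_increase))
  invisible(x)
}

#' Percent diversity increase implied by a log-scale increase
#'
#' @param ln_increase log-scale change, typically |slope| x time span.
#' @return 100 x (exp(ln_increase) - 1). Report tables round this to the
#'   nearest integer.
#' @export
percent_increase <- function(ln_increase) {
  stopifnot(all(is.finite(ln_increase)))
  100 * expm1(ln_increase)
}

#' Bonferroni correction for multiple trend tests
#'
#' @param p_values vector of P values in [0, 1].
#' @param m number of comparisons (default `length(p_values)`).
#' @param alpha family-wise error rate (default 0.05).
#' @return list: `p_adjusted` (min(1, p x m)), `threshold` (alpha / m), `m`,
#'   `alpha`.
#' @export
bonferroni_correct <- function(p_values, m = length(p_values), alpha = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1), m >= 1)
  list(p_adjusted = pmin(1, p_values * m), threshold = alpha / m,
       m = m, alpha = alpha)
}

#' Palaeolatitudinal summary of a spatial sample
#'
#' Summarizes the absolute palaeolatitude of the member grid cells of an
#' equal-spread sample: the median, the interquartile range and the full
#' range, as drawn on latitude-versus-richness plots.
#'
#' @param sample an accepted `spatial_sample`, or a numeric vector of
#'   latitudes (degrees).
#' @param cells the parent `grid_cells` (needed when `sample` is a
#'   `spatial_sample`).
#' @return named list: `median`, `q25`, `q75`, `min`, `max` of |palaeolat|.
#' @export
latitude_summary <- function(sample, cells = NULL) {
  lat <- if (is.numeric(sample)) sample else {
    stopifnot(isTRUE(sample$accepted), !is.null(cells))
    cells$centroid_lat[match(sample$cells, cells$cell_id)]
  }
  stopifnot(length(lat) >= 1)
  a <- abs(lat)
  q <- stats::quantile(a, c(0.25, 0.5, 0.75), names = FALSE)
  list(median = q[2], q25 = q[1], q75 = q[3], min = min(a), max = max(a))
}

#' Table of trend fits with Bonferroni-corrected P values
#'
#' @param fits list of `trend_fit` objects.
#' @param alpha family-wise error rate for the corrected threshold.
#' @return data.frame, one row per fit: series, family, slope, se, p,
#'   p_bonferroni, df, ln_increase, percent_increase (rounded to integer, as
#'   in report tables); attribute `p_threshold` holds alpha / m.
#' @export
trend_table <- function(fits, alpha = 0.05) {
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits))
    return(data.frame(series = character(0), family = character(0),
                      slope = numeric(0), se_slope = numeric(0),
                      p_slope = numeric(0), p_bonferroni = numeric(0),
                      df = integer(0), ln_increase = numeric(0),
                      percent_increase = numeric(0)))
  p <- vapply(fits, function(f) f$p_slope, numeric(1))
  bc <- bonferroni_correct(p, alpha = alpha)
  out <- data.frame(
    series = vapply(fits, function(f) f$series_label, character(1)),
    family = vapply(fits, function(f) f$family, character(1)),
    slope = vapply(fits, function(f) f$slope, numeric(1)),
    se_slope = vapply(fits, function(f) f$se_slope, numeric(1)),
    p_slope = p,
    p_bonferroni = bc$p_adjusted,
    df = vapply(fits, function(f) f$df, integer(1)),
    ln_increase = vapply(fits, function(f) f$ln_increase, numeric(1)),
    percent_increase = round(vapply(fits, function(f) f$percent_increase,
                                    numeric(1))),
    stringsAsFactors = FALSE)
  attr(out, "p_threshold") <- bc$threshold
  out
}
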