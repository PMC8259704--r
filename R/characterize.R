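#' Autocorrelation profile of one employee's rest series
#'
#' Pearson correlation between the series and its lagged copy at lags
#' `1..max_lag`. Rest lengths are long-tailed (holidays), so they are
#' log-transformed by default: the log retains relative order while
#' shrinking the tail. A constant series has no defined ACF and yields
#' `NA`s flagged with attribute `constant`.
#'
#' @param x Positive numeric series (e.g. `rest_after` hours).
#' @param max_lag Largest lag (default 14, about two weeks of shifts).
#' @param log_transform Apply `log()` first (requires positive values).
#' @return Numeric vector of length `max_lag` (may contain `NA` where a
#'   lagged segment is constant).
#' @export
employee_acf <- function(x, max_lag = 14L, log_transform = TRUE) {
  n <- length(x)
  if (n <= max_lag) stopf("series length %d must exceed max_lag %d",
                          n, max_lag)
  if (log_transform) {
    if (any(x <= 0)) stopf("log transform requires positive values")
    x <- log(x)
  }
  if (stats::sd(x) == 0) {
    return(structure(rep(NA_real_, max_lag), constant = TRUE))
  }
  vapply(seq_len(max_lag), function(l) {
    a <- x[1:(n - l)]
    b <- x[(l + 1):n]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
}

#' Cluster-average autocorrelation profile
#'
#' Lag-wise arithmetic mean of member ACFs; members whose ACF is entirely
#' undefined are excluded and counted.
#'
#' @param acfs List of equal-length ACF vectors (from [employee_acf()]).
#' @return Mean ACF per lag with attribute `n_excluded`.
#' @export
cluster_mean_acf <- function(acfs) {
  defined <- !vapply(acfs, function(a) all(is.na(a)), logical(1))
  if (!any(defined)) stopf("no member has a defined ACF")
  m <- do.call(cbind, acfs[defined])
  structure(rowMeans(m, na.rm = TRUE), n_excluded = sum(!defined))
}

#' Dimension-wise average distance between two clusters
#'
#' Mean over all cross-pairs (one member from each cluster) of the
#' single-dimension distance. By default the distance is the square root
#' of the symmetric alpha divergence of that dimension's codebooks, so
#' the three dimension-wise values are on the scale of (and recombine
#' comparably to) the total employee distance; `aggregate =
#' "divergence"` averages the raw divergences instead.
#'
#' @param cluster_a,cluster_b Lists of codebook triples (the members of
#'   each cluster).
#' @param dim One of `"shift_length"`, `"rest_after"`, `"start_hour"`.
#' @param alpha Divergence order.
#' @param aggregate `"sqrt_divergence"` (default) or `"divergence"`.
#' @return Nonnegative number, symmetric in the two clusters.
#' @export
dimensionwise_cluster_distance <- function(cluster_a, cluster_b, dim,
                                           alpha = 0.5,
                                           aggregate = c("sqrt_divergence",
                                                         "divergence")) {
  aggregate <- match.arg(aggregate)
  if (!dim %in% ws_dims()) stopf("unknown dimension %s", dim)
  if (!length(cluster_a) || !length(cluster_b)) stopf("empty cluster")
  vals <- unlist(lapply(cluster_a, function(a) {
    vapply(cluster_b, function(b) {
      alpha_divergence(a[[dim]], b[[dim]], alpha)
    }, numeric(1))
  }))
  if (aggregate == "sqrt_divergence") mean(sqrt(vals)) else mean(vals)
}

#' Fraction of shifts followed by short rest
#'
#' @param series Named list of `work_series` (one cluster).
#' @param threshold_h Rest threshold in hours (e.g. 13 for "quickish"
#'   returns).
#' @return Fraction of shifts with `rest_after` strictly below the
#'   threshold, with attribute `n` (number of rests pooled).
#' @export
short_rest_fraction <- function(series, threshold_h = 13) {
  if (!length(series)) stopf("empty cluster")
  if (threshold_h <= 0) stopf("threshold must be positive")
  rests <- unlist(lapply(series, `[[`, "rest_after"), use.names = FALSE)
  structure(mean(rests < threshold_h), n = length(rests))
}

#' Compare short-rest fractions of two clusters
#'
#' Pearson chi-squared test (no continuity correction) on the 2 x 2 table
#' of short versus long rests in the two clusters.
#'
#' @param series_a,series_b Named lists of `work_series`.
#' @param threshold_h Rest threshold in hours.
#' @return List with `fraction_a`, `fraction_b`, `statistic`, `df`,
#'   `p_value`.
#' @export
compare_short_rest <- function(series_a, series_b, threshold_h = 13) {
  fa <- short_rest_fraction(series_a, threshold_h)
  fb <- short_rest_fraction(series_b, threshold_h)
  na <- attr(fa, "n"); nb <- attr(fb, "n")
  tab <- rbind(c(round(fa * na), na - round(fa * na)),
               c(round(fb * nb), nb - round(fb * nb)))
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(fraction_a = as.numeric(fa), fraction_b = as.numeric(fb),
       statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Welch's unequal-variance t test
#'
#' Thin wrapper over [stats::t.test()] returning the statistic,
#' Satterthwaite degrees of freedom and p value.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
welch_t <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    stopf("both groups are constant; the Welch statistic is undefined")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
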