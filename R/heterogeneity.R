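#' Variation between adjacent sections
#'
#' The study's small-scale heterogeneity statistic: for every pair of
#' consecutive non-missing sections, `|x[i+1] - x[i]| / pair mean * 100`.
#' Missing sections break adjacency -- no pair spans a gap. Pairs whose mean
#' is zero are undefined; they are excluded from the summary but counted.
#'
#' @param series Numeric per-section values in section order; `NA` marks a
#'   missing section.
#' @param denominator `"pair_mean"` (symmetric, default) or `"first"`
#'   (relative to the upstream section of the pair).
#' @return Object of class `adjacent_variation`: list with `pairs` (data
#'   frame `i`, `j`, `variation_pct`), `mean`, `sd`, `n_pairs`,
#'   `n_undefined`.
#' @examples
#' adjacent_variation(c(100, 150))$pairs$variation_pct  # 40
#' @export
adjacent_variation <- function(series,
                               denominator = c("pair_mean", "first")) {
  denominator <- match.arg(denominator)
  ok <- !is.na(series)
  if (sum(ok) < 2) stop("need at least 2 non-missing sections")
  i <- which(ok[-length(series)] & ok[-1])
  if (length(i) == 0L)
    stop("no adjacent non-missing pair (all neighbours span gaps)")
  a <- series[i]; b <- series[i + 1L]
  den <- if (denominator == "pair_mean") (a + b) / 2 else a
  v <- ifelse(den == 0, NA_real_, abs(b - a) / den * 100)
  defined <- !is.na(v)
  structure(list(
    pairs = data.frame(i = i, j = i + 1L, variation_pct = v),
    mean = mean(v[defined]),
    sd = stats::sd(v[defined]),
    n_pairs = sum(defined),
    n_undefined = sum(!defined),
    denominator = denominator
  ), class = "adjacent_variation")
}

#' @export
print.adjacent_variation <- function(x, ...) {
  cat(sprintf("Adjacent-section variation: %.1f +/- %.1f%% (n = %d%s)\n",
              x$mean, x$sd, x$n_pairs,
              if (x$n_undefined) paste0(", ", x$n_undefined, " undefined")
              else ""))
  invisible(x)
}

#' Micrometre-scale variation within a section
#'
#' Relative range `(max - min) / max * 100` of the per-column thickness
#' profile within one section (detected, uncensored columns only).
#'
#' @param profile Numeric per-column thickness values; `NA` = undetected.
#' @return Percentage, or `NA` (flagged with a warning) if the maximum is 0.
#' @export
micro_scale_variation <- function(profile) {
  v <- profile[!is.na(profile)]
  if (length(v) < 2) stop("need at least 2 detected columns")
  if (max(v) == 0) {
    warning("maximum thickness is 0; micro-scale variation undefined")
    return(NA_real_)
  }
  (max(v) - min(v)) / max(v) * 100
}

#' Fold range of a positive series
#'
#' @param series Positive per-section values (`NA` allowed, ignored).
#' @return `max / min` (dimensionless).
#' @export
fold_range <- function(series) {
  v <- series[!is.na(series)]
  if (any(v <= 0)) stop("fold_range requires strictly positive values")
  max(v) / min(v)
}

#' Longitudinal linear trend of a per-section series
#'
#' Ordinary least-squares fit of the series against position, with the
#' relative increase over the fitted span: `percent_increase =
#' (fit(max pos) - fit(min pos)) / fit(min pos) * 100`.
#'
#' @param series Per-section values (`NA` = missing, dropped pairwise).
#' @param positions Section positions in cm.
#' @return Object of class `trend_summary`: `slope` (units/cm),
#'   `intercept`, `r_squared`, `pearson_r`, `percent_increase` (`NA` and
#'   flagged if the fitted start is <= 0), `ci` (95% confidence interval of
#'   the slope), `n`.
#' @export
longitudinal_trend <- function(series, positions) {
  stopifnot(length(series) == length(positions))
  ok <- !is.na(series) & !is.na(positions)
  if (sum(ok) < 3) stop("need at least 3 points")
  y <- series[ok]; x <- positions[ok]
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else 0
  r2 <- min(max(r2, 0), 1)
  f0 <- intercept + slope * min(x)
  f1 <- intercept + slope * max(x)
  pct <- if (f0 > 0) (f1 - f0) / f0 * 100 else NA_real_
  r <- unname(sign(slope) * sqrt(r2))
  structure(list(
    slope = slope, intercept = intercept,
    r_squared = r2, pearson_r = r,
    percent_increase = pct,
    start_nonpositive = f0 <= 0,
    ci = {
      n <- length(y)
      se <- sqrt(sum(stats::resid(fit)^2) / (n - 2) /
                   sum((x - mean(x))^2))
      slope + c(-1, 1) * stats::qt(0.975, n - 2) * se
    },
    n = sum(ok)
  ), class = "trend_summary")
}

#' @export
print.trend_summary <- function(x, ...) {
  cat(sprintf("Linear trend: slope %.3g /cm (R2 = %.2f, n = %d)",
              x$slope, x$r_squared, x$n))
  if (!is.na(x$percent_increase))
    cat(sprintf("; %+.0f%% over the fitted span", x$percent_increase))
  cat("\n")
  invisible(x)
}

#' Welch two-sample comparison of section groups
#'
#' @param a,b Numeric vectors (each with at least 2 values; `NA` dropped).
#' @return List: `t`, `p_value`, `mean_a`, `sd_a`, `mean_b`, `sd_b`. If both
#'   groups have zero variance and equal means, `t = 0` and `p = 1` by
#'   convention.
#' @export
group_compare <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p_value = 1, mean_a = mean(a), sd_a = 0,
                  mean_b = mean(b), sd_b = 0))
    return(list(t = Inf * sign(mean(a) - mean(b)), p_value = 0,
                mean_a = mean(a), sd_a = 0, mean_b = mean(b), sd_b = 0))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_a = mean(a), sd_a = stats::sd(a),
       mean_b = mean(b), sd_b = stats::sd(b))
}

#' Representativeness of aggregated multi-section samples
#'
#' Simulates sampling larger areas by averaging windows of `k` adjacent
#' sections: for each window size the curve reports the mean absolute
#' relative deviation of window means from the global mean (%). Windows
#' never span a missing-section gap. At `k` equal to the full (gap-free)
#' series length the deviation is exactly 0.
#'
#' @param series Per-section values (`NA` = missing).
#' @param window_sizes Integer vector of window sizes `k >= 1`.
#' @param mode `"sliding"` (default; all maximal windows) or `"disjoint"`
#'   (non-overlapping windows).
#' @return Object of class `representativeness_curve`: data frame `k`,
#'   `deviation_pct`, `n_windows`.
#' @export
representativeness_curve <- function(series, window_sizes,
                                     mode = c("sliding", "disjoint")) {
  mode <- match.arg(mode)
  ok <- !is.na(series)
  if (!any(ok)) stop("series is entirely missing")
  gmean <- mean(series[ok])
  if (gmean == 0) stop("global mean is zero; relative deviation undefined")
  window_sizes <- as.integer(window_sizes)
  if (any(window_sizes < 1)) stop("window sizes must be >= 1")
  if (any(window_sizes > length(series)))
    stop("window sizes exceed the series length")
  runs <- split(which(ok), cumsum(!ok)[ok])   # maximal gap-free runs
  out <- lapply(window_sizes, function(k) {
    wmeans <- unlist(lapply(runs, function(idx) {
      n <- length(idx)
      if (n < k) return(numeric(0))
      starts <- if (mode == "sliding") seq_len(n - k + 1L) else
        seq(1L, n - k + 1L, by = k)
      vapply(starts, function(s) mean(series[idx[s:(s + k - 1L)]]),
             numeric(1))
    }), use.names = FALSE)
    if (length(wmeans) == 0L)
      return(data.frame(k = k, deviation_pct = NA_real_, n_windows = 0L))
    data.frame(k = k,
               deviation_pct = mean(abs(wmeans - gmean) / abs(gmean)) * 100,
               n_windows = length(wmeans))
  })
  structure(do.call(rbind, out),
            class = c("representativeness_curve", "data.frame"))
}

#' Contrast two section windows
#'
#' Plain means and sds over two non-overlapping index ranges plus the
#' difference of means; used to quantify localized step changes in, e.g.,
#' the relative abundance of a taxon.
#'
#' @param series Per-section values (`NA` = missing, dropped).
#' @param range_a,range_b Integer vectors of section indices; must not
#'   overlap and must retain at least 2 non-missing sections each.
#' @return List: `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b`,
#'   `difference` (`mean_b - mean_a`).
#' @export
window_contrast <- function(series, range_a, range_b) {
  if (length(intersect(range_a, range_b)) > 0)
    stop("ranges must not overlap")
  a <- series[range_a]; a <- a[!is.na(a)]
  b <- series[range_b]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each range needs >= 2 non-missing sections")
  list(mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
       mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
       difference = mean(b) - mean(a))
}
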