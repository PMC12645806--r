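# Group-level resampling statistics for per-subject difference series.
# A "difference series" is a subjects x timepoints matrix of per-subject
# condition differences (RMS or mean amplitude).

#' Pointwise bootstrap sign test
#'
#' Resamples subjects with replacement `n_iter` times; at each timepoint the
#' proportions of resampled group means falling above and below zero are
#' recorded. A timepoint is significant when either proportion reaches
#' `1 - alpha` (two-sided criterion; exact zeros count for neither side).
#'
#' @param series `subjects x timepoints` matrix of per-subject differences.
#' @param n_iter Number of bootstrap iterations (default 1000).
#' @param alpha Significance level (default 0.01).
#' @param seed Optional integer seed.
#' @return A `bootstrap_result`: list with `prop_pos`, `prop_neg`, `mask`,
#'   `p` (pointwise `1 - max(prop)`), `alpha`, `n_iter`.
#' @export
bootstrap_sign_test <- function(series, n_iter = 1000, alpha = 0.01,
                                seed = NULL) {
  series <- as.matrix(series)
  n_sub <- nrow(series)
  if (n_sub < 2) stop("need at least 2 subjects")
  if (!is.null(seed)) set.seed(seed)
  idx <- matrix(sample.int(n_sub, n_sub * n_iter, replace = TRUE),
                n_iter, n_sub)
  counts <- matrix(0, n_iter, n_sub)
  for (j in seq_len(n_sub))
    counts[, j] <- rowSums(idx == j)
  means <- counts %*% series / n_sub              # n_iter x timepoints
  prop_pos <- colMeans(means > 0)
  prop_neg <- colMeans(means < 0)
  pmax_ <- pmax(prop_pos, prop_neg)
  structure(list(prop_pos = prop_pos, prop_neg = prop_neg,
                 mask = pmax_ >= 1 - alpha, p = 1 - pmax_,
                 alpha = alpha, n_iter = n_iter),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %d timepoints, %d iterations, alpha %g; %d significant\n",
              length(x$mask), x$n_iter, x$alpha, sum(x$mask)))
  invisible(x)
}

#' Contiguous significant clusters
#'
#' Maximal runs of significant timepoints, with durations and weights
#' (weight = sum of `1 - p` over member timepoints).
#'
#' @param mask Logical vector, or a `bootstrap_result`.
#' @param fs Sampling rate in Hz.
#' @param p Optional pointwise p-values for the weights (taken from the
#'   `bootstrap_result` when one is supplied).
#' @return Data frame with `start`, `end` (sample indices), `duration_s`,
#'   `weight`; zero rows when nothing is significant.
#' @export
find_clusters <- function(mask, fs, p = NULL) {
  if (inherits(mask, "bootstrap_result")) {
    if (is.null(p)) p <- mask$p
    mask <- mask$mask
  }
  if (!any(mask))
    return(data.frame(start = integer(0), end = integer(0),
                      duration_s = numeric(0), weight = numeric(0)))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  weight <- if (is.null(p)) rep(NA_real_, length(starts)) else
    mapply(function(s, e) sum(1 - p[s:e]), starts, ends)
  data.frame(start = starts, end = ends,
             duration_s = (ends - starts + 1L) / fs, weight = weight)
}

max_cluster_stat <- function(clusters, statistic = c("duration", "weight")) {
  statistic <- match.arg(statistic)
  if (nrow(clusters) == 0) return(0)
  max(switch(statistic, duration = clusters$duration_s, clusters$weight))
}

split_half_diffs <- function(control, statistic) {
  # per subject: difference between the summaries of two random halves
  t(vapply(control, function(trials) {
    n <- if (is.matrix(trials)) nrow(trials) else dim(trials)[1]
    half <- sample.int(n, n %/% 2)
    statistic(trials, half) - statistic(trials, setdiff(seq_len(n), half))
  }, numeric(series_length(control))))
}

series_length <- function(control) {
  x <- control[[1]]
  if (is.matrix(x)) ncol(x) else dim(x)[length(dim(x))]
}

default_statistic <- function(trials, subset) {
  if (is.matrix(trials)) colMeans(trials[subset, , drop = FALSE])
  else colMeans(colMeans(trials[subset, , , drop = FALSE], dims = 1))
}

#' Null distribution of cluster statistics by split-half resampling
#'
#' Estimates the noise floor of the cluster analysis from a single control
#' condition: each subject's control trials are repeatedly split into two
#' random halves, the half-difference series are submitted to the same
#' pointwise bootstrap procedure as the main analysis (at the
#' cluster-forming level `cluster_alpha`), and the maximum significant
#' cluster statistic of each split is recorded. The 95th percentile of this
#' distribution is the threshold used for false-discovery control.
#'
#' @param control List over subjects; each element a `trials x timepoints`
#'   matrix of per-trial control series (or a 3-d array whose subsets
#'   `statistic` can summarise).
#' @param n_splits Number of split-half resamples (default 1000).
#' @param cluster_alpha Cluster-forming significance level (default 0.05).
#' @param n_iter Bootstrap iterations per split.
#' @param fs Sampling rate in Hz.
#' @param statistic Function `(trials, subset) -> series` summarising a
#'   subset of one subject's trials (default: mean over trials).
#' @param cluster_stat `"duration"` (default) or `"weight"`.
#' @param seed Optional integer seed.
#' @return A `null_distribution`: list with `values` (one max-cluster
#'   statistic per split), `threshold` (95th percentile), `cluster_alpha`,
#'   `n_splits`, `statistic`.
#' @export
null_cluster_distribution <- function(control, n_splits = 1000,
                                      cluster_alpha = 0.05, n_iter = 200,
                                      fs = 256,
                                      statistic = default_statistic,
                                      cluster_stat = "duration",
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_trials <- vapply(control, function(x)
    if (is.matrix(x)) nrow(x) else dim(x)[1], numeric(1))
  if (any(n_trials < 2)) stop("every subject needs >= 2 control trials")
  vals <- vapply(seq_len(n_splits), function(s) {
    diffs <- split_half_diffs(control, statistic)
    bt <- bootstrap_sign_test(diffs, n_iter = n_iter, alpha = cluster_alpha)
    max_cluster_stat(find_clusters(bt, fs), cluster_stat)
  }, numeric(1))
  structure(list(values = vals,
                 threshold = stats::quantile(vals, 0.95, names = FALSE),
                 cluster_alpha = cluster_alpha, n_splits = n_splits,
                 statistic = cluster_stat, fs = fs),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d splits (%s, cluster alpha %g); 95th percentile threshold = %.4g\n",
              x$n_splits, x$statistic, x$cluster_alpha, x$threshold))
  invisible(x)
}

#' @export
plot.null_distribution <- function(x, observed = NULL, ...) {
  graphics::hist(x$values, breaks = 30,
                 xlab = sprintf("max cluster %s", x$statistic),
                 main = "split-half null distribution", ...)
  graphics::abline(v = x$threshold, lty = 2)
  if (!is.null(observed)) graphics::abline(v = observed, col = 2, lty = 2)
  invisible(x)
}

#' Cluster durations under trial subsampling
#'
#' Re-runs the main two-condition comparison on random subsamples of the
#' trials (a stability check mirroring the 50%-of-trials resampling
#' analysis): per resample, `fraction` of each subject's trials in each
#' condition is drawn, per-subject difference series are formed from the
#' subsample summaries, and the maximum significant cluster statistic is
#' recorded.
#'
#' @param cond_a,cond_b Lists over subjects of per-trial series matrices
#'   (as in [null_cluster_distribution()]).
#' @param fraction Fraction of trials per condition per subject.
#' @param n_resamples Number of resamples.
#' @param alpha Significance level of the pointwise bootstrap.
#' @param n_iter Bootstrap iterations per resample.
#' @param fs Sampling rate in Hz.
#' @param statistic Subset summary function, as in
#'   [null_cluster_distribution()].
#' @param cluster_stat `"duration"` or `"weight"`.
#' @param seed Optional integer seed.
#' @return Numeric vector of max-cluster statistics, one per resample.
#' @export
half_split_resampling_comparison <- function(cond_a, cond_b, fraction = 0.5,
                                             n_resamples = 100,
                                             alpha = 0.01, n_iter = 200,
                                             fs = 256,
                                             statistic = default_statistic,
                                             cluster_stat = "duration",
                                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(cond_a) == length(cond_b))
  vapply(seq_len(n_resamples), function(r) {
    diffs <- t(mapply(function(a, b) {
      na <- if (is.matrix(a)) nrow(a) else dim(a)[1]
      nb <- if (is.matrix(b)) nrow(b) else dim(b)[1]
      sa <- sample.int(na, max(1, round(fraction * na)))
      sb <- sample.int(nb, max(1, round(fraction * nb)))
      statistic(a, sa) - statistic(b, sb)
    }, cond_a, cond_b))
    bt <- bootstrap_sign_test(diffs, n_iter = n_iter, alpha = alpha)
    max_cluster_stat(find_clusters(bt, fs), cluster_stat)
  }, numeric(1))
}

#' Distribution of recovery latencies by bootstrap resampling
#'
#' Estimates when a planted or observed condition deficit ends: in each of
#' `n_iter` iterations the subjects are resampled with replacement and the
#' end of the deficit run is recorded — the last sample of the contiguous
#' run of deficit-sign resampled group means anchored at the interval start
#' (the interruption offset, where the deficit is maximal). An iteration
#' counts as showing a deficit only when that anchored run lasts at least
#' `min_run_s`; iterations without one (as expected when no effect is
#' present) are counted separately and excluded from the quantiles.
#'
#' @param series `subjects x timepoints` difference-series matrix.
#' @param interval Length-2 integer vector of sample indices bounding the
#'   analysis interval (from the interruption offset to the start of the
#'   baseline window).
#' @param n_iter Bootstrap iterations (default 1000).
#' @param fs Sampling rate in Hz (for `min_run_s`).
#' @param direction Sign of the deficit (`-1` when the test condition lies
#'   below the control, `+1` above); by default inferred from the observed
#'   group mean at the interval start.
#' @param min_run_s Minimum anchored-run duration for an iteration to count
#'   (default 0.1 s; a genuine post-interruption deficit outlasts this, a
#'   null fluctuation essentially never does).
#' @param threshold_frac The deficit is deemed over once the resampled mean
#'   recovers to within this fraction of its own value at the interval
#'   start (default 0.05). A strictly-zero criterion would let noise keep
#'   the run alive past the true recovery point with probability 1/2 per
#'   noise correlation length; the small threshold removes that late tail
#'   at a sub-sample early cost.
#' @param seed Optional integer seed.
#' @return A `latency_distribution`: list with `latency_sample` (per
#'   retained iteration), `n_empty`, `median`, `quantiles` (2.5/25/75/97.5%).
#' @export
recovery_latency <- function(series, interval, n_iter = 1000, fs = 256,
                             direction = NULL, min_run_s = 0.1,
                             threshold_frac = 0.05, seed = NULL) {
  series <- as.matrix(series)
  if (length(interval) != 2 || interval[1] > interval[2])
    stop("interval must be two ascending sample indices")
  interval <- as.integer(interval)
  if (!is.null(seed)) set.seed(seed)
  n_sub <- nrow(series)
  win <- series[, interval[1]:interval[2], drop = FALSE]
  if (is.null(direction)) direction <- sign(mean(win[, 1]))
  if (direction == 0) direction <- -1
  min_run <- max(1L, round(min_run_s * fs))
  n_slope <- max(3L, round(0.08 * fs))
  lat <- vapply(seq_len(n_iter), function(i) {
    m <- direction * colMeans(win[sample.int(n_sub, n_sub, replace = TRUE), ,
                                  drop = FALSE])
    if (m[1] <= 0) return(NA_integer_)
    theta <- threshold_frac * m[1]
    deficit <- m > theta
    run_end <- if (all(deficit)) length(deficit)
               else which(!deficit)[1] - 1L
    if (run_end < min_run) return(NA_integer_)
    # extrapolate from the threshold crossing to the zero crossing using the
    # local slope of the recovering deficit
    lo <- max(1L, run_end - n_slope + 1L)
    tt <- lo:run_end
    slope <- -stats::coef(stats::lm.fit(cbind(1, tt), m[tt]))[2]
    extra <- if (is.finite(slope) && slope > 0)
      min(round(m[run_end] / slope), 3L * n_slope) else 0
    interval[1] + min(run_end + as.integer(extra), ncol(win)) - 1L
  }, integer(1))
  ok <- !is.na(lat)
  structure(list(latency_sample = lat[ok], n_empty = sum(!ok),
                 median = if (any(ok)) stats::median(lat[ok]) else NA_real_,
                 quantiles = if (any(ok))
                   stats::quantile(lat[ok], c(0.025, 0.25, 0.75, 0.975))
                 else NULL,
                 interval = interval, direction = direction),
            class = "latency_distribution")
}

#' @export
print.latency_distribution <- function(x, ...) {
  cat(sprintf("<latency_distribution> %d iterations with a significant sample (%d empty); median latency sample %s\n",
              length(x$latency_sample), x$n_empty, format(x$median)))
  invisible(x)
}
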